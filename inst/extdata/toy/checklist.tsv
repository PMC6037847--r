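drug_name	accepted_species	known_adulterants	toxic
DrugA	Genus alpha	Genus spurium	1
DrugB	Genus beta;Genus gamma		0
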