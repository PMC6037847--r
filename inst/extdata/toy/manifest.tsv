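sample_id	declared_drug	source_code	status
T001	DrugA	ZH	sequenced
T002	DrugA	HH	sequenced
T003	DrugB	YS	sequenced
T004	DrugB	ZH	no_amplification
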