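Package: seedbarcode
Title: DNA Barcode Authentication of Seed Herbal Medicines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for DNA-barcode authentication of seed
    traditional-medicine materials. Builds and validates local reference
    libraries of ITS2 and psbA-trnH barcode sequences linked to a
    pharmacopoeia drug checklist, extracts marker regions in silico from
    amplicon sequences using primer anchors, identifies query sequences by
    alignment-based percent-identity search with a 98% top-match rule,
    assesses species and drug discrimination with Kimura 2-parameter
    distances, neighbor-joining trees and bootstrap supports, classifies
    market-survey samples into a five-way authentication outcome, and
    aggregates survey batches. A Kimura 2-parameter sequence simulator
    generates reference libraries and full market surveys with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
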