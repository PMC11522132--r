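Package: en2splice
Title: Transcription Outcome Prediction for the En2 Cryptic Splice Site in
    Knockout-First Mouse Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the consequences of the cryptic splice donor inside the
    En2 splice-acceptor sequence carried by IKMC/IMPC knockout-first (tm1a)
    and derived (tm1b, tm1e) mouse alleles. Provides frame-aware translation
    of the 115 bp retained En2 insert, classification of every critical-exon
    start/end phase combination into readthrough, frameshift, En2-induced
    stop codon or other, bulk application of the classifier to allele-design
    tables with Ensembl/BioMart-style exon phases, aggregation of IMPC-style
    phenotype-hit and lacZ-expression tables by predicted outcome category,
    and a seeded synthetic-data generator producing phase-consistent gene
    models and phenotype cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'cassette.R'
    'phase.R'
    'translate.R'
    'classify.R'
    'ingest.R'
    'pheno.R'
    'simulate.R'
    'pipeline.R'
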