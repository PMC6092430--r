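Package: lynchpept
Title: Neoepitope Prioritization and Immune Microenvironment Scoring for
    Hereditary Mismatch-Repair-Deficient Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for Lynch-syndrome (mismatch-repair
    deficient) tumours: co-segregation screening of germline variants in
    affected/unaffected pedigree panels, consequence calling and mutant
    protein construction (including frameshift translation to the novel
    stop), wildtype/mutant 9-mer peptide pair enumeration, an
    HLA-binding and TCR-binding filter cascade with configurable nM
    thresholds, DNA/RNA allele-depth concordance checks, marker-gene
    selection from reference immune-cell expression profiles (average
    rank score and marker evaluation score), single-sample gene-set
    enrichment (ssGSEA) immune scoring with permutation presence calls,
    and a checkpoint/antigen-presentation expression report.  A
    synthetic-data generator produces every input the pipeline consumes,
    with truth ledgers for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
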