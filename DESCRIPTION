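Package: npscreen
Title: Network-Propagation Screening of Addiction-Regulating miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational screen for microRNAs that regulate drug
    addiction-related gene programs. Each miRNA family's direct-target
    perturbation is propagated through a directed transcription-regulation
    network by a random walk with restart; the propagated per-gene effects
    are correlated with log-transformed reliability scores of known
    addiction genes through a weighted running-sum enrichment statistic
    (NPES) with permutation significance, Benjamini-Hochberg FDR control
    and leading-edge extraction. Significant families are intersected with
    miRNAs passing a median-normalised two-group microarray fold-change
    filter to yield ranked candidates. Also included: strict readers and
    writers for the tabular and FASTA inputs, a synthetic-data generator
    with planted ground truth for end-to-end validation, canonical seed
    site scanning (8mer, 7mer-m8, 7mer-A1, 6mer) on 3'UTR inserts,
    seed-mutant construct design, dual-luciferase normalisation and
    2^-delta-delta-Ct relative quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
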