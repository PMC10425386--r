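Package: ampliclass
Title: Classification of CRISPR-Cas9 Editing Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies deep amplicon-sequencing reads from CRISPR-Cas9
    editing experiments into DNA double-strand-break repair outcomes:
    non-homologous end joining (+/-1 bp indels), microhomology-mediated
    deletions (alternative end joining), homology-directed-repair knock-in,
    NHEJ-mediated knock-in with donor orientation, and a residual class.
    Models SpCas9 blunt and 1-nt 5'-overhang staggered cuts, derives the
    expected knock-in alleles for single-stranded oligonucleotide and
    double-stranded DNA donors, quantifies outcomes as fractions of mapped
    and mutated reads, renders top-variant profiles around the cut site,
    and computes coverage-based large-deletion proportions and indices for
    long-read amplicons. Includes a synthetic read simulator with ground
    truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
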