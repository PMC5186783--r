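Package: hydroscan
Title: Phylum-Wide Survey of Hydrogenase Gene Systems in Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for surveying [NiFe] hydrogenase (hox, hup),
    maturation (hyp), and nitrogenase (nif) gene systems across annotated
    bacterial genomes. Detects homologs by exact affine-gap local alignment
    with reciprocal-best-hit confirmation, calls functional capability from
    three minimal criteria (structural gene set, maturation gene set,
    conserved catalytic residues), verifies catalytic and oxygen-tolerance
    motifs by reference-anchored global alignment, classifies gene-cluster
    arrangements into canonical patterns, and summarises co-occurrence of
    hydrogenase and nitrogenase genes by habitat and morphological
    subsection. Ships a synthetic-genome generator with planted truth so
    every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    yaml,
    ape,
    Biostrings,
    rtracklayer,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
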