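Package: crisprcensus
Title: Census of CRISPR-Cas and Alternative Viral Defence Systems in
    Draft-Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CRISPR arrays, cas operons, circular viral genomes and
    alternative defence systems (restriction-modification, abortive
    infection/toxin-antitoxin, BREX) in collections of draft microbial
    genomes, and computes completeness-corrected incidence statistics:
    single-copy-gene completeness estimates, a conservative contiguous-gap
    probability model for missing a cas1-length segment, a Poisson-binomial
    tail for the aggregate detection deficit, genus-weighted logistic
    regression for lifestyle association, and spacer-protospacer matching
    against viral populations. Ships a seeded synthetic-community generator
    so the full census pipeline is testable without external data.
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
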