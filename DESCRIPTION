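Package: btrnai
Title: Resistance Durability Modelling and Bioassay Statistics for Bt + RNAi Pyramided Cotton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating transgenic cotton pyramids that combine a
    Bacillus thuringiensis (Bt) toxin with RNA-interference (RNAi) protection
    against Helicoverpa armigera. Provides a deterministic two-locus
    population-genetic simulator of resistance evolution under four deployment
    strategies (Bt alone, RNAi alone, sequential release, pyramid) with refuge
    sweeps and durability tables; cotton leaf bioassay statistics including
    transgene efficacy, the index of multiplicative survival with its
    one-sample test, one-way ANOVA with Tukey HSD compact letter displays,
    strain t-tests, two-way ANOVA and qPCR relative quantification; an
    exact-match k-mer specificity screen for dsRNA trigger fragments against
    candidate off-target transcripts; and a synthetic-data generator that
    emulates the full bioassay design for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
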