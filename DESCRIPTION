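Package: polystate
Title: Translational-State Classification from Polysome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-stage, three-fraction polysome profiling
    experiments. Classifies mRNA isoforms into transcriptional and
    translational regulation states (repressed, derepressed, monosome shift)
    from input, monosome and polysome abundance contrasts with
    Benjamini-Hochberg false-discovery control; performs compositional
    analysis of sucrose-gradient fraction profiles (closure, fraction
    differences, Welch's t-test between conditions); quantifies qPCR results
    with the delta-delta-Ct method; runs permutation gene-set enrichment
    against disease gene lists with an exact hypergeometric oracle; and
    simulates complete experiments with planted translational states so every
    stage of the pipeline can be verified against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    limma,
    generics,
    ggplot2,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
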