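Package: sedprime
Title: Carbon-13 Tracer Mass Balance for Sediment Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying organic-matter mineralization, priming,
    carbon use efficiency and microbial secondary production from 13C-labelled
    substrate incubations of anoxic sediments. Converts between delta notation
    and atom fractions, partitions evolved dissolved inorganic carbon into
    substrate-derived and indigenous fractions by two-end-member isotope
    mixing, quantifies the priming effect against unamended controls,
    estimates new biomass from 13C-labelled hydrolyzable amino acids,
    fits first-order and two-pool (2G) degradation kinetics, and computes
    the amino-acid degradation index. Includes a forward simulator of the
    incubation experiment for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
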