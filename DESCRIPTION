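Package: synadapt
Title: Simulating and Analysing Rapid Syntactic Expectation Adaptation in
    Self-Paced Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how readers adapt their syntactic
    expectations to the statistics of a new linguistic environment.
    Implements a Dirichlet-multinomial belief-updating model over
    sentence-structure categories (main verb, reduced relative clause,
    other) with a surprisal link to reading times, builders for two
    garden-path self-paced-reading designs (mixed 50/50 exposure and a
    blocked two-group exposure), a generator for synthetic word-by-word
    reading-time data with known effect structure, and the standard
    analysis chain for such experiments: outlier exclusion, mixed-model
    length correction, region aggregation, and factorial mixed-effects
    regressions measuring how garden-path (ambiguity) effects change with
    exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
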