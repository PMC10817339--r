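Package: dualrecall
Title: Dual-Retrieval Modeling of Repeated Free Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing categorized-list free recall experiments with
    three successive recall tests. Implements the dual-retrieval multinomial
    processing tree model of recall (direct access D, forgetting F,
    reconstruction R, and per-test familiarity judgments J1-J3), with
    maximum-likelihood estimation, G-squared goodness of fit against
    chi-square(1), and delta-G-squared likelihood-ratio tests of
    cross-condition parameter equality. Also provides the adjusted ratio of
    clustering (ARC) statistic for category clustering in recall output
    orders, a synthetic-experiment generator emulating a 2 (list organization)
    x 3 (judgment-of-learning condition) between-participants design, a
    transcript scoring pipeline with an upper-sided median + 1.5 IQR outlier
    screen, and planned one-way ANOVA / LSD reporting with effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
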