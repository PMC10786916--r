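Package: coopunish
Title: Multinomial Cooperation-and-Punishment Modelling for the
    Prisoner's Dilemma with Costly Punishment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the two-tree multinomial processing tree (MPT) model of
    cooperation and costly punishment to categorical decision data from
    Prisoner's Dilemma experiments with a costly punishment option.
    Provides product-multinomial maximum-likelihood estimation with
    multistart optimization, G-squared goodness of fit, nested
    equality-restriction tests with delta-G-squared statistics and
    Cohen's w effect sizes, noncentral chi-square power and sensitivity
    analysis, and a trial-level simulator of the full experimental design
    (partner base-rate manipulation, graded punishment investments and
    fines, payoff accounting). Results are returned as tibbles with
    broom-style tidy() and glance() methods and ggplot2 autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
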