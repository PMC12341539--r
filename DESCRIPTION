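Package: prejump
Title: Grey Relational Ranking of Pre-Jump Height Determinants in Trampoline Gymnasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for building and ranking an indicator
    system of pre-jump height determinants in juvenile trampoline gymnasts.
    Provides expert-panel screening of candidate indicators, per-block
    indicator reduction via diagnostics-gated principal-component factor
    analysis (KMO sampling adequacy, Bartlett's sphericity test, varimax
    rotation, representative-indicator selection), Deng's grey relational
    analysis against a criterion sequence with strong/moderate/weak
    classification, and a moment-matched synthetic cohort generator whose
    sample means, standard deviations and criterion correlations reproduce a
    published moment specification exactly. All user-facing functions take
    data frames and return tibbles; results carry tidy(), glance() and
    autoplot() methods.
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
    jsonlite,
    MASS,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
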