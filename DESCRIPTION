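Package: asbscreen
Title: Cost-Effectiveness of Low-Dose CT Lung-Cancer Screening in
    Asbestos-Exposed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A five-state Markov cohort model comparing organised low-dose
    thoracic CT lung-cancer screening with usual care in populations with
    occupational asbestos exposure. Provides stratum-specific lung-cancer
    incidence inputs, a synthetic cohort generator emulating a French
    post-occupational surveillance cohort, annual and biennial screening
    strategies with stage shift and overdiagnosis, discounted cost and
    quality-adjusted life-year accumulation, incremental cost-effectiveness
    ratios, probabilistic sensitivity analysis with gamma-beta-normal
    parameter draws, one-way tornado analyses, scenario grids over
    subgroups, start ages and screen intervals, and cost-effectiveness
    acceptability curves.
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
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
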