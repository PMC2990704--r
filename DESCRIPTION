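Package: crcscreen
Title: Cost-Effectiveness Microsimulation of Colorectal Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model of colorectal cancer (CRC) screening in
    average-risk adults aged 50 to 75. Implements an adenoma-carcinoma
    natural-history state-transition model with a one-year cycle; seven
    screening modalities (guaiac and immunochemical stool tests, fecal DNA,
    colonoscopy, flexible sigmoidoscopy, and CT colonography) with imperfect
    adherence, follow-up colonoscopy cascades, polypectomy, procedural
    complications and post-polypectomy surveillance; discounted cost and
    quality-adjusted life-year accounting in 2008 Canadian dollars; a
    first-order Monte Carlo microsimulation engine and a deterministic
    cohort-expectation engine; natural-history calibration against reference
    incidence and mortality targets; incremental cost-effectiveness analysis
    with strong and extended dominance; and second-order probabilistic
    sensitivity analysis.
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
    purrr,
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
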