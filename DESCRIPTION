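Package: ffaquant
Title: Automated Quantification of Fundus Fluorescein Angiography Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch pipeline for quantifying retinal vascular integrity from
    fundus fluorescein angiography (FFA) frame series across species (mouse,
    non-human primate, human). Decodes heterogeneous image formats, recovers
    per-frame acquisition times, registers frames within a session (FAST/ORB
    style keypoints for primates, phase correlation for rodents), segments the
    macula with an ETDRS grid, masks large vessels, and extracts regional
    intensity-versus-time profiles. Temporal leakage metrics (cumulative
    intensity over common timepoints, angiographic phase summaries, decay
    profiles, morning-versus-evening percent change) feed a normality-gated
    statistical engine (Anderson-Darling dispatch to paired t or exact Wilcoxon
    signed-rank, nested-eye mixed-effects models, Sidak adjustment). A fully
    synthetic FFA study generator with programmable circadian leakage provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jpeg,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
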