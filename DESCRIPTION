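Package: dopplerperf
Title: Quantitative Color-Doppler Tissue Perfusion and Single-Vessel Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies blood flow in color-Doppler cine loops of focal lesions by two
    complementary routes: dynamic tissue perfusion measurement (tissue flow velocity,
    tissue resistive index, tissue perfusion intensity over a region of interest) and
    single-vessel flow measurement (flow velocity, resistive index, volume flow with
    automatic Doppler-angle correction). Includes a lossless cine container with
    colorbar lookup-table decoding of per-pixel velocities, cardiac-cycle segmentation
    of perfusion traces, group statistics with a normality gate, ROC analysis with
    Youden-optimal cut-offs and paired DeLong comparison of correlated AUCs, and a
    calibrated synthetic cine generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
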