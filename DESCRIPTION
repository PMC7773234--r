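Package: toothtrack
Title: Agreement and Systematics Analysis for Video- and Sensor-Coded
    Toothbrushing Sessions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for validating automated motion-tracking (MT) records of
    toothbrushing against video observation (VO). Reconciles the two
    differently sampled coded behaviour streams onto a common half-second
    interval grid by majority vote, quantifies their agreement (matching
    proportions, confusion matrices with adjacency classes, Cohen's kappa),
    and computes behavioural systematics outcomes per session (per-area
    brushing durations, event counts, consistency, isochronicity and the
    Toothbrushing Systematics Index) together with the nonparametric group
    comparisons used in method-agreement studies. Includes a synthetic
    session generator emulating habitual and post-instruction brushing with
    realistic sensor error structure, so the full pipeline can be exercised
    end to end without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
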