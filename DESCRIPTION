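Package: prezone
Title: Zone-Based Selection of Low Performers from Weakly Correlated
    Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements the prediction-by-zone (PreZone) procedure for
    selecting low-performing individuals from multivariate biomarker
    profiles when no predictor correlates usefully with the response.
    Scores from an unknown cohort are mapped onto a known cohort's scale
    by rank and z-score transfer, partitioned into per-variable zones
    anchored at the profiles of known low performers, and selected by a
    Manhattan distance cascade over zone labels. Includes the ordinary
    least-squares baseline, selection-evaluation metrics (egg-productivity
    improvement and under-average rate), multi-stage continuous selection,
    and a synthetic flock generator emulating serum-protein panels of
    laying hens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
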