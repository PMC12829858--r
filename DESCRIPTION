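Package: ffaconcord
Title: Cross-Species Concordance Scoring of Free Fatty Acid Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing targeted free fatty acid (FFA) GC-MS
    concentration panels between a patient cohort and animal depression
    models. Implements control-referenced z-score standardization, the
    S-score model-fidelity statistic, the radar-polygon area (AERC)
    summary, normality-gated per-analyte group comparisons with optional
    covariate adjustment, model ranking, and a log-normal synthetic cohort
    generator for fully reproducible desk-scale analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
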