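Package: ludosim
Title: Preclinical-to-Clinical Internal Dosimetry for 177Lu Radiopharmaceuticals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for MIRD-schema internal dosimetry of 177Lu-labeled
    radiopharmaceuticals from small-animal biodistribution data. Reads and
    summarizes multi-animal percent-injected-dose-per-gram tables, extrapolates
    mouse organ concentrations to whole-organ uptake in a reference adult,
    fits mono-exponential organ time-activity curves, integrates them into
    time-integrated activity, and computes organ absorbed doses with a
    generated S-value matrix, unit-density-sphere tumor self-dose, effective
    dose, and tumor-to-organ dose ratios. Includes SPECT semi-quantification
    helpers (cylinder calibration factor, ROI to percent-injected-dose-per-cc)
    and a synthetic biodistribution generator with known ground-truth kinetics
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
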