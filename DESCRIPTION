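Package: gevisim
Title: Simulation and Spike-Detection Analysis of Positive- and
    Negative-Going Voltage Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates one-photon fluorescence imaging of genetically encoded
    voltage indicators (GEVIs) of either signal polarity and quantifies how
    indicator polarity and sensitivity affect spike detection as neuronal
    labeling density grows. Generates ground-truthed voltage traces, spatial
    footprints, out-of-focus background neurons and fluorescence movies with
    photobleaching and signal-proportional noise; converts voltage to
    fluorescence through a linear F_min/F_max indicator model; provides trace
    processing (exponential bleach correction, dF/F, moving-percentile
    baselines, double-exponential kinetics fits, fluorescence-voltage curves);
    detects spike-like events with a shift-invariant wavelet transform (MODWT,
    sym4) and recovers single-neuron traces from movies by iterative
    pixel-weight refinement; and evaluates inferred spike trains against
    ground truth with intersection-over-union error, including density by
    sensitivity by polarity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
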