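Package: bsdetect
Title: EEG-Free Detection of Anesthesia-Induced Burst-Suppression from BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects anesthesia-induced burst-suppression directly from BOLD fMRI
    time series, without concurrent EEG. The detector builds a carpet plot
    (z-scored voxel-by-frame matrix of cortical time series), extracts temporal
    principal components by singular value decomposition, and flags runs in which
    a component correlates asymmetrically with the cortex (median cortex-wide
    Pearson r above a species-specific threshold). Companion tools segment
    concurrent EEG into burst and suppression epochs by band power, convert the
    binary envelope into a hemodynamic model via a two-gamma response function and
    bandpass projection, quantify PC-to-model correspondence by lagged
    cross-correlation, produce voxelwise correlation and Fisher-Z maps, compare
    maps by neighborhood cross-correlation, and compute region-of-interest
    amplitude and Welch spectral metrics. A seeded synthetic phantom generator
    (two-state envelope, HRF-convolved engaged voxels, matched noise, drift,
    controllable hemodynamic lag, amplitude-modulated EEG) supports fully
    self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
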