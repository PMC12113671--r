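Package: frostspec
Title: Hyperspectral Identification of Freeze-Damaged Corn Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometrics pipeline for classifying freeze damage in single
    corn (Zea mays) seeds from visible/near-infrared hyperspectral images.
    Provides ENVI cube input/output with dark/white reflectance calibration,
    Otsu-threshold seed segmentation and mean-spectrum extraction, standard
    normal variate and Savitzky-Golay (5-point cubic) preprocessing,
    feature-wavelength selection by the successive projections algorithm
    (SPA) and by autocorrelation peaks of two-dimensional correlation
    spectroscopy (2DCOS) synchronous spectra, SPA-2DCOS wavelength fusion,
    Kennard-Stone sample partitioning, KNN/LDA/SVM classifiers, and
    chance-corrected accuracy metrics. A synthetic seed-spectra and cube
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    class,
    e1071,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
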