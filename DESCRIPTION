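Package: ramanmsi
Title: Raman Spectral Classification of Microsatellite Instability in
    Colorectal Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for discriminating normal, microsatellite
    stable (MSS) and microsatellite unstable (MSI-H) colorectal tissue from
    point Raman spectra. Provides a synthetic spectrum generator emulating a
    three-class, thirty-sample study design; standard normal variate (SNV)
    preprocessing with fingerprint-region truncation; fold-internal data
    augmentation by Poisson shot noise and bounded wavenumber shifts; three
    classifier families (PCA-LDA, RBF-kernel SVM and a one-dimensional
    convolutional neural network) behind a common fit/predict-probability
    contract; repeated nested cross-validation with sample-grouped splits,
    log-loss hyperparameter selection and majority-vote sample labelling;
    and post-hoc interpretation via difference spectra, Raman band
    assignment and occlusion sensitivity maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
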