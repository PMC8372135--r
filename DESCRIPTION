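Package: evoofuse
Title: Multi-Sensor One-Class Authentication of Extra Virgin Olive Oil
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening pipeline for extra-virgin-olive-oil (EVOO) authenticity
    from hyphenated fluorescence, visible and near-infrared transflectance
    spectra. Provides dark/white reference correction, saturation filtering and
    scan averaging; a synthetic study generator emulating an oil library with
    admixtures and replicate measurement runs; chemometric preprocessing (SNV,
    SNV-detrend, Savitzky-Golay derivatives, wavelet features, spectral
    splitting); five one-class classifiers (SIMCA, kNN, PCA residuals,
    Mahalanobis, one-class SVM) trained on EVOO only with grouped inner
    cross-validation; AUROC-based model ranking with per-sensor quota
    selection; high-level vote fusion with two decision-threshold scenarios;
    and per-class rate tables, per-fraction detection curves and a
    reference-chemistry conformity checker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
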