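Package: gliodwi
Title: Multi-b-Value Diffusion MRI Modelling for Glioma Genotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise fitting of four diffusion-weighted MRI signal models
    (mono-exponential, intravoxel incoherent motion, stretched-exponential and
    continuous-time random walk, the latter built on a numerically robust
    Mittag-Leffler evaluator) to multi-b-value acquisitions, volume-of-interest
    parameter extraction, and the downstream group-comparison and ROC machinery
    used to predict IDH mutation and 1p/19q codeletion status in adult diffuse
    glioma. Includes a synthetic-cohort generator with Rician noise so the full
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    pROC,
    car,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
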