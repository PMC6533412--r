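Package: gojrad
Title: Multi-Modal PET/MRI Radiomics for Gastroesophageal Tumour Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-tumour radiomics pipeline for integrated PET/MRI of
    oesophageal and gastroesophageal-junction cancer. Computes 12 first-order
    histogram and 12 second-order grey-level co-occurrence matrix (GLCM)
    features from up to five co-registered modalities (SUV, T1-weighted,
    T2-weighted, high-b diffusion, ADC), screens all feature pairs with
    unsupervised k-means (k = 2) clustering against a binary metastasis
    label, fits a linear discriminant boundary, tests group separability by
    two-group MANOVA (Wilks' lambda), and quantifies feature robustness to
    one-voxel segmentation dilation and erosion via relative error and the
    intraclass correlation coefficient ICC(2,1). Includes a synthetic
    multi-modal tumour-phantom generator with controllable texture
    correlation length, used to emulate labelled cohorts end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
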