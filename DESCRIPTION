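Package: rtOutcome
Title: Radiobiological Evaluation of Radiotherapy Treatment Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-based radiobiological evaluation of external-beam
    radiotherapy dose distributions. Implements the linear-quadratic
    Poisson tumour control probability (TCP) model, the
    Lyman-Kutcher-Burman (LKB) and relative-seriality normal tissue
    complication probability (NTCP) models on isoeffect-converted
    (EQDx) voxel doses, the composite complication-free tumour control
    probability P+, intrafractional-motion dose blurring with an
    anisotropic Gaussian kernel, dose-volume histogram and geometry
    metrics (DX%, Dice, coverage, minimum distances), constraint
    checking, exact paired Wilcoxon signed-rank comparison, and a
    seeded synthetic prostate-phantom cohort generator with
    simultaneous-integrated-boost dose painting for end-to-end testing
    without patient data. Includes minimal DICOM RT Dose / RT
    Structure Set readers and writers and a lossless internal case
    format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
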