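Package: fetquant
Title: Delineation, Quantification and Evaluation of Amino-Acid PET Brain
    Tumor Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for threshold-based biological tumor volume (BTV)
    delineation on amino-acid PET images of the brain (such as [18F]FET
    PET), extraction of the semi-quantitative clinical metrics used in
    neuro-oncology (TBRmean, TBRmax, BTV, peak uptake location), dynamic
    time-activity-curve analysis (time-to-peak and kinetic pattern
    classification), evaluation of candidate delineations against a
    reference (Dice similarity, voxel-level confusion metrics, metric
    concordance, longitudinal congruence), and generation of synthetic
    static and dynamic brain PET phantoms with ground-truth lesion masks
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
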