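Package: larvascreen
Title: Image-Based Larval Size Screening for a Fly Model of NGLY1 Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a whole-organism 96-well
    chemical-modifier screening pipeline for a Drosophila model of NGLY1
    deficiency. Provides a synthetic plate-image and well-area generator with
    full ground truth, the screen's larval-detection algorithm (empty-well
    background estimation by edge exclusion and surface interpolation,
    difference-image segmentation, per-well area measurement with artifact
    metrics), plate quality control via the Z-prime factor, per-well Z-scores
    against in-plate negative controls, replicate merging and the
    two-of-three-replicates pre-hit rule, multi-stage artifact triage and
    unique-compound accounting, and validation-stage developmental-timing
    analyses (eclosion timecourses, fold changes, size comparisons, and
    four-parameter logistic dose-response fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
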