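Package: gtvconc
Title: Geometric Concordance Analysis of Radiotherapy Gross Target Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how gross target volumes (GTVs) contoured for
    esophageal-cancer radiotherapy agree across imaging strategies. Simulates
    paired planning-CT and PET digital thorax phantoms with cylindrical
    esophageal tumors and known contour perturbations, auto-delineates targets
    by a mediastinal-window CT wall rule and an SUV-threshold rule
    (max of an absolute SUV of 2.5 and 20% of SUVmax), computes pairwise
    geometric concordance metrics (center-of-mass displacement, 3D vector,
    volume, cranio-caudal length, maximum transverse diameter, conformity
    index, degree of inclusion, Dice, Hausdorff distance), and runs paired
    nonparametric cohort statistics stratified by tumor location.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
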