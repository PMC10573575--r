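Package: choroquant
Title: Volumetric Choroidal Thickness and Vascularity Quantification from
    OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the choroid from swept-source OCT intensity volumes:
    depth-resolved optical attenuation compensation, dynamic-programming
    segmentation of Bruch's membrane and the choroidal-scleral interface,
    en face choroidal thickness maps, Otsu binarization of choroidal vessels
    and per-A-scan choroidal vascularity index (CVI) maps, rigid en face
    registration of longitudinal visits, fovea-centered regional summaries
    with optic-nerve-head and artifact exclusion masks, and linear models
    with cluster-robust (sandwich) variance for fellow-eye designs.  A
    synthetic OCT phantom and cohort generator with known ground truth
    supports validation of every stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
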