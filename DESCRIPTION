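Package: retwalk
Title: Retinal Vessel Segmentation with Centerline-Seeded Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of blood vessels in retinal fundus
    photographs. Vessels are enhanced with a multiscale Hessian-based
    vesselness filter, centerlines are located from the divergence of the
    normalized gradient vector field and corrected with a morphological
    skeleton (multi-orientation bottom-hat, Otsu binarization, Zhang-Suen
    thinning), seeds are planted automatically around the centerlines, and
    the final mask is obtained by solving the seeded random-walker
    Dirichlet problem on a vesselness-weighted 8-connected pixel lattice.
    Includes a synthetic fundus phantom generator with exact ground truth
    and pixelwise sensitivity/specificity/accuracy evaluation inside the
    camera field of view.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    graphics,
    grDevices,
    jsonlite,
    methods,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
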