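Package: myeliquant
Title: Automated Quantification of Myelination in Organoid Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying myelination in human myelinating organoid
    ("myelinoid") cultures from multi-channel confocal z-stacks. Implements
    per-plane adaptive thresholding of a myelin marker (MBP or CNP) followed by
    a shape- and intensity-based filter cascade that rejects cell bodies and
    debris, multi-scale blob subtraction, 3D object assembly across z-planes,
    and normalization of myelin volume to axonal density measured from an NF-H
    channel. Also provides single-cell sheath morphometrics from trace tables,
    nearest-neighbor oligodendrocyte density, Sholl analysis, g-ratio
    regression, and cluster-aware fold-change estimation with a stratified
    myelinoid-level bootstrap. A seeded synthetic-stack generator with
    voxel-level ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
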