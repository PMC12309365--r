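Package: aive
Title: AI-Directed Voxel Extraction and Organelle Quantification for Volume EM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Refines AI-derived membrane probability maps from volume electron
    microscopy by multiplying them with contrast-normalized electron signal
    intensities (AI-directed voxel extraction), then reconstructs organelle
    surfaces by isosurface extraction and quantifies membrane contact sites,
    per-organelle morphometrics (sphericity, elongation, skeleton length,
    nanotunnels, intrusion cavities), and the geometric probability that a
    linear intrusion survives sectioning intact (inverse Buffon's needle).
    Includes a synthetic phantom generator emulating anisotropic FIB-SEM
    volumes and disagreeing AI model predictions so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    tiff,
    EBImage,
    igraph,
    yaml,
    jsonlite,
    stats,
    tools,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
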