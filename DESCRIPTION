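Package: slotpipe
Title: Simulation, Reconstruction and Correlative Analysis for Scanning
    Laser Optical Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mesoscale optical projection tomography of cleared,
    resin-embedded specimens in the style of Scanning Laser Optical
    Tomography (SLOT). Provides a seeded synthetic lung-lobe phantom
    generator (pleural shell, alveolar voids, branching airways, optional
    dense fibrotic patches), closed-form acquisition planning (depth of
    field, lateral resolution, angular sampling, mosaic bookkeeping), a
    two-channel forward projector for parallel and fan-like scan geometries
    with Beer-Lambert transmission and fluorescence line integrals, sinogram
    preprocessing including de-shearing of fan-beam data along the angle
    axis, filtered back projection, three-landmark correlative reslice
    alignment with flat and curved (polyline) reslices, tiled-mosaic
    stitching with iterative translation-basis estimation and linear
    blending, and density-based screening of dense regions via anisotropic
    diffusion, gradient magnitude and marker-based watershed segmentation.
    Volumes and sinograms are read and written as multipage TIFF with YAML
    sidecars, or as MRC (mode 2).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
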