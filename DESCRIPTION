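Package: vesselssl
Title: Semi-Supervised 3D Vessel Segmentation for Sparsely Annotated Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting blood vessels in large high-resolution 3D
    volumes (for example hierarchical phase-contrast tomography of lung biopsies)
    when ground-truth labels are sparse, annotated only on a cadence of slices.
    Implements two semi-supervised training schemes around a compact 3D
    convolutional encoder-decoder written from scratch: a dual-decoder
    consistency-regularization network whose two decoders carry opposed
    effective-receptive-field biases (dilation-biased and erosion-biased
    attention branches), and an expectation-maximization pseudo-labelling loop
    with a fixed confidence threshold. Includes a seeded synthetic vascular
    phantom generator with slice-cadence label sparsification, volume assembly
    and normalization, overlapping 3D patch planning with label-density
    filtering and overlap-blended stitching, dense and annotation-aware Dice
    evaluation, slice overlay rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    RNifti,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
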