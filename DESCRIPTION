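Package: lgncnn
Title: Emergent Receptive-Field and Lateral-Connectivity Geometry in an
    LGN-Inspired Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the geometry that emerges in the early layers of a
    biologically inspired convolutional network for grayscale image
    classification. The network carries a single-filter pre-processing layer
    modelled on the lateral geniculate nucleus and a learned lateral
    connectivity kernel acting on the first convolutional layer, in analogy
    with the horizontal connectivity of primary visual cortex. The package
    implements the network and its two-phase training, fits
    Laplacian-of-Gaussian and Gabor receptive-profile models to learned
    filters, re-maps the lateral kernel into position-orientation coordinates,
    extracts orientation-tuning (hypercolumn) profiles, builds association
    fields as streamlines of an orientation-weighted vector field, and
    compares them with circular-arc integral curves of the sub-Riemannian
    structure on R^2 x S^1. Synthetic generators (Gabor banks, co-circular
    connectivity kernels, oriented-contour image datasets) provide ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
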