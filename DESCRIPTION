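Package: ligafem
Title: Finite-Element Micromechanics of Collagen-Elastin Ligament Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric finite-element study of a ligament modelled as
    parallel collagen fibres bridged by elastin blocks and anchored to bone
    at both ends. Builds fibre and homogeneous sheet geometries, voxelizes
    them into conforming hexahedral meshes, solves small-strain linear
    elastostatics with a sparse direct solver, and applies three loading
    protocols (tensile traction, shear traction, prescribed 30-degree bone
    rotation). Post-processing summarises von Mises stress and displacement
    per tissue component, estimates stress-strain slopes, and sweeps elastin
    content from 0 to 33.5 percent to quantify how elastin governs shear and
    rotational rigidity. A companion module estimates elastin content from
    two-channel (collagen second-harmonic / elastin autofluorescence)
    microscopy images by a pixel-ratio rule, with a synthetic image
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
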