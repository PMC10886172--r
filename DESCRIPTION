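Package: aaamech
Title: Structural Finite-Element Mechanics of Abdominal Aortic Aneurysms with
    Intraluminal Thrombus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for the structural analysis of abdominal
    aortic aneurysms (AAA) that carry a non-uniform intraluminal thrombus
    (ILT). Generates idealized AAA boundary surfaces with a sector-limited,
    Gaussian-bulged thrombus; performs surface smoothing, thickness-based
    fragmentation, normal offsetting, boundary-loop stitching and watertight
    body assembly; builds conforming tetrahedral meshes of the wall and
    thrombus with a shared interface; assigns per-element local material
    frames (circumferential, axial, radial) from a vessel centerline and
    dispersed collagen-fiber directions; evaluates linear-elastic
    (Saint Venant-Kirchhoff), Mooney-Rivlin and Holzapfel-Gasser-Ogden
    constitutive models; solves the quasi-static two-body problem under
    incremental intraluminal pressure with a total-Lagrangian Newton method,
    follower loads and a tied wall-thrombus interface; and post-processes
    principal stresses, equivalent strains, tensile-strength limits, regional
    (ILT-covered versus ILT-free) summaries and volume metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    jsonlite,
    tidyr
Config/testthat/edition: 3
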