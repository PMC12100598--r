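Package: tubulaR
Title: Parametric Tubulin Tubule Models and Debye-Equation SAXS Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds coarse-grained structural models of supramolecular
    tubulin assemblies (inverted helical tubules, conical spiral tubules,
    hexagonal and oblique bundles, and simple microtubule lattices) as
    ordered sets of subunit poses, computes their solution small-angle
    X-ray scattering (SAXS) curves with the Debye equation over bead
    models with solvent and hydration-shell contrast, and fits scattering
    data: two-state linear-combination decomposition of kinetic curve
    families, singular-value-decomposition rank analysis, isosbestic-point
    detection, non-negative mixture fitting of model components, and
    grid-based recovery of structural parameters such as tubule radii and
    helical pitch. A synthetic-data module generates subunits, assemblies,
    noisy curves and kinetic series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    bio3d,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
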