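Package: monofem
Title: Non-Conforming Hexahedral Finite Elements for Cardiac Monodomain
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solves the monodomain reaction-diffusion equation of cardiac
    electrophysiology on structured hexahedral meshes using trilinear (Q1),
    triquadratic (Q2) and incompatible-modes non-conforming (Q1NC) elements.
    The non-conforming unknowns are eliminated per element by static
    condensation (Schur complement), so the global system keeps Q1 size. A
    semi-implicit (IMEX) integrator treats diffusion implicitly with a system
    matrix factorised once and the modified Aliev-Panfilov reaction terms
    explicitly; a fully-implicit backward-Euler comparator is included.
    Ships plane-wave conduction-velocity, anisotropic-cuboid benchmark and
    S1-S2 spiral-wave protocols with activation-map post-processing and
    legacy-VTK/CSV export.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
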