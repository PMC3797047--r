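Package: rdfsvd
Title: Reduced Representation of Fluid Radial Distribution Functions by
    Singular Value Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven (discrete) molecular dynamics for hard-sphere and
    square-well fluids, estimation of the radial distribution function g(r)
    over parameter sweeps, and compression of the resulting curve family by
    singular value decomposition with low-order polynomial surrogates for the
    coefficient vectors.  The compact representation reconstructs g(r) at any
    interpolated packing fraction or attractive strength.  Includes physical
    validation tools (static structure factor and its positivity, dilute-limit
    checks, virial pressure against the Carnahan-Starling equation of state)
    and Ornstein-Zernike integral-equation baselines (Percus-Yevick,
    hypernetted chain, Rogers-Young).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
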