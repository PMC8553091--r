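Package: actoflow
Title: Filament-Level Brownian Dynamics of Lamellipodial Actin Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bead-spring Brownian dynamics simulation of a lamellipodial actin
    network undergoing retrograde flow past a focal adhesion acting as a
    molecular clutch. Filaments are semiflexible bead-spring chains with
    excluded volume, permanent and dynamic crosslinkers, age-dependent bond
    severing, leading-edge pushing and motor pulling forces, and a
    capsule-shaped high-friction adhesion region with stochastic binding
    kinetics. Includes scenario drivers (adhesion-strength sweeps,
    polymerization inhibition, arc and microspike formation, branching) and a
    mechanical-characterization rig measuring network elastic moduli from the
    virial stress tensor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
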