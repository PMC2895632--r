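Package: knotpath
Title: Energy Landscapes, Folding Pathways and Kinetics of Knotted Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for exploring the potential energy landscape of
    coarse-grained protein models with non-trivial backbone topology.
    Implements a smooth three-site-per-residue Go-type associative-memory
    potential with analytic gradients, basin-hopping global optimisation,
    doubly-nudged elastic band transition-state searches with a
    chain-crossing avoidance scheme, hybrid eigenvector-following saddle
    refinement, kinetic transition networks with harmonic transition state
    theory rates, graph-transformation mean first-passage times, recursive
    free-energy regrouping, disconnectivity graphs, and knot classification
    of backbone traces via the Alexander polynomial determinant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
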