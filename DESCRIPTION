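Package: foldbroker
Title: Claim-Based Brokering of Fold-Tree Kinematics for Constrained
    Conformational Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Internal-coordinate polypeptide kinematics on fold trees
    (directed, rooted, acyclic coordinate-propagation graphs with jumps and
    cuts), plus a broker that collects formalized claims from independent
    client movers, builds a single consensus fold tree satisfying all of
    them, and enforces per-client degree-of-freedom access during Metropolis
    Monte Carlo sampling via passports and a protected conformation.
    Includes client movers for fragment insertion, rigid template chunks,
    beta-strand pairing jumps, rigid-body docking through center-of-mass
    virtual residues, and cyclic-coordinate-descent loop closure, together
    with programmatic toy fixtures emulating three protocol archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
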