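Package: pmfenrich
Title: PMF-Enriched Sampling with Knowledge-Based Pseudo-Potentials of Mean Force
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pseudo-potentials of mean force (p-PMFs) by Boltzmann
    inversion of radial and torsional distributions accumulated over sets of
    biomolecular structures under a quasi-homogeneity approximation, converts
    them into a normalized partition-function bias with analytic gradients,
    and couples that bias to a reference Hamiltonian through a renormalized
    hybrid Hamiltonian with a fluctuating coupling factor.  Includes a
    desk-scale stochastic-dynamics engine for toy chain topologies, a
    multi-bias path-sampling comparator with history-dependent Gaussian
    deposition, seeded synthetic-structure generators, and an analysis layer
    for free-energy landscapes, conformer-class partitions, transition
    kinetics and escape-time acceleration.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
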