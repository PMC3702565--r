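Package: pathfe
Title: Free-Energy Profiles Along Principal-Curve Transition Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes one-dimensional free-energy profiles along curved
    transition pathways in high-dimensional conformational space. Builds a
    principal curve from unrestrained-trajectory ensembles (straight-line
    projection, binning, per-bin averaging, smooth sinusoidal curve fitting,
    arc-length reparametrization), sets up tangent-only umbrella restraints
    under a local linear approximation, runs Hamiltonian replica exchange
    over the umbrella windows, and reconstructs the profile with the
    weighted histogram analysis method including block-averaged error
    propagation. Ships a toy overdamped Langevin engine, curved-valley test
    potentials, a synthetic-ensemble generator, and brute-force free-energy
    oracles so the full pipeline is testable without a molecular-dynamics
    engine. Includes trajectory analyses: projection time series, domain
    center distances, RMSD tables, and hydrogen-bond-based salt-bridge
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics
Suggests:
    bio3d,
    tidyr,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
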