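Package: tcrpmhc
Title: Comparative Analysis of TCR-pMHC Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Descriptor extraction and two-group statistical comparison for
    molecular-dynamics ensembles of T-cell receptor / peptide / MHC complexes.
    Computes per-residue hydrogen-bond footprints (normalized frequency
    scores), solvent-accessible surface areas, root mean square fluctuations,
    a panel of sixteen named interface distances, and the five-angle plus
    one-distance description of the relative orientation of the TCR variable
    domains.  Group differences between more and less immunogenic peptide
    variants are quantified by the total variation distance and a normalized
    mean distance, calibrated by a trajectory-level permutation test.  A
    synthetic-data module generates toy complexes with planted group effects
    so the full pipeline can be exercised and validated without access to
    production trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
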