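Package: hyperbar
Title: Trajectory Analysis of Membrane-Embedded Ion Channels Under Hyperbaric Gas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of a
    tetrameric ion channel embedded in a phospholipid bilayer, aimed at
    comparing control, hydrostatic-pressure and dissolved-gas conditions.
    Reads GROMACS GRO trajectories and NDX index groups, performs
    periodic-boundary cleanup (make whole, center, compact packing),
    Kabsch superposition RMSD series, gromos conformational clustering,
    Z-axis mass-density profiles, per-residue radial-distribution-function
    solvation layouts, united-atom acyl-chain order parameters with
    prochiral hydrogen reconstruction, grid-based rolling-probe
    (solvent-excluded) volumes, channel pore-radius profiling and
    binding-site geometry. A synthetic system generator with analytic
    ground truth (gas partitioning between leaflets, channel-shell
    dehydration, prescribed chain order) makes every estimator testable
    without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
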