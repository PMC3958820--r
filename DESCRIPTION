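Package: lipidmc
Title: Local-Move Monte Carlo Simulation of United-Atom Phospholipid Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atomistic Metropolis Monte Carlo sampling of united-atom
    phospholipids (DPPC) under the constant-bond-length approximation.
    Implements chain-breakage/closure local moves with Jacobian-corrected
    acceptance, crankshaft and internal-coordinate moves, NPT volume moves
    for 2D-periodic bilayer patches, an implicit-solvent sigmoidal
    distance-dependent dielectric, and a trajectory-analysis suite
    (energy-histogram fits and fluctuation heat capacity, Schlitter
    configurational entropy, head-group torsion distributions, electron
    density profiles and bilayer thickness, P-N vector orientation, area
    per lipid and area compressibility, and center-of-mass mean square
    displacement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
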