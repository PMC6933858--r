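Package: probemap
Title: Probe Hot-Spot Mapping and Pharmacophore Models from Druggability
    Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyzes cosolvent (druggability) molecular dynamics
    trajectories of a protein in a box of drug-fragment probe molecules.
    Accumulates per-probe-type voxel occupancies on a 0.5 Angstrom grid,
    converts them to inverse-Boltzmann free energies, merges high-occupancy
    voxels into hot spots and clusters hot spots into ranked druggable
    sites; profiles per-residue probe binding scores (sum of inverse
    squared contact distances), calls high-affinity residues, ranks
    residue-probe interactions by their frequency of occurrence, extracts
    snapshots in which all top-ranked interactions co-occur, and exports
    pharmacophore models as Pharmit session JSON for virtual screening.
    Includes a synthetic-fixture generator that plants probe-binding
    events with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
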