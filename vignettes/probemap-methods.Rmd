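---
title: "Mapping probe hot spots and building pharmacophores from druggability simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping probe hot spots and building pharmacophores from druggability simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probemap)
```

## The problem

Druggability (cosolvent) simulations are molecular dynamics runs of a
target protein in explicit water doped with small drug-fragment probe
molecules — typically isopropanol, acetamide, imidazole, acetate,
isopropylamine and isobutane, at about one probe per twenty waters. Where
probes repeatedly park on the protein surface, both the strength of the
interaction (enthalpy) and its frequency of occurrence (an entropic
signal) point to binding sites capable of accommodating drug-like
molecules. `probemap` turns such a trajectory into (1) per-probe *hot
spots* and ranked *druggable sites*, (2) per-residue probe-affinity
profiles, (3) a frequency-ranked table of residue–probe interactions, (4)
snapshots in which the dominant interactions co-occur, and (5)
pharmacophore models exported as Pharmit session JSON for virtual
screening. Screening itself (Pharmit, docking) happens outside the
package; a `pec50_from_ec50()` helper is provided for annotating hit
tables.

## The model, stage by stage

**Superposition.** All frames are rigidly fitted (least-squares Kabsch,
on Cα atoms matched by chain, residue number and insertion code) onto a
reference PDB. Every downstream coordinate — grid voxels, hot-spot
centers, feature spheres — lives in this reference frame. Superposition
is idempotent, and all scores are invariant to rigid motion of the input
frames. Frames are assumed image-wrapped (probes whole and in the
protein's periodic image); the package performs no periodic-boundary
unwrapping.

**Grid occupancy.** Space is voxelized on an absolute 0.5 Å lattice
(voxel index = `floor(x / edge)`, so voxel addresses are reproducible
across runs and the grid extends wherever probes go). For each frame and
probe copy, the copy is counted — into the single voxel containing its
heavy-atom centroid — if and only if at least one of its heavy atoms is
within 2.5 Å of a protein heavy atom. Hydrogens are stored but excluded
from all distance computations, with one deliberate exception noted
below.

**Inverse-Boltzmann energies.** A voxel's count is converted to a free
energy ΔG = −RT·ln(count / expected), with RT = 0.596 kcal/mol at 300 K.
The expected count spreads each probe type's counted probe-frames
uniformly over the *accessible* voxels of the grid bounding box (box
voxels minus voxels containing a protein heavy atom in any frame). A
box-volume background was the alternative; the accessible-volume
convention was chosen because the protein interior is not available to
probes, and the choice is exposed through the grid object rather than
hard-coded into results. Empty voxels get +∞ so they can never become
hot spots.

**Hot spots and sites.** Voxels at or below the energy cutoff (default
−1.0 kcal/mol — conservative, chosen so noise-only systems yield no hot
spots; configurable) are merged greedily per probe type: candidates are
visited in descending occupancy (ties broken by lexicographic voxel
index, making centers deterministic and anchored on the strongest
signal), each joining the nearest existing hot spot closer than 5.5 Å or
seeding a new one. Hot-spot centers are occupancy-weighted centroids;
energies are recomputed from summed counts. Hot spots of *all* probe
types are then pooled and single-linked at 5.5 Å; clusters of at least
six hot spots become druggable sites, ranked by ascending site score.
The 5.5 Å figure serves both the voxel→hot-spot merge and the
hot-spot→site linkage in the standard convention; the two knobs are
independent parameters (`merge_distance`, `site_link_distance`) so
either can be varied. All 5.5 Å comparisons are strict (`<`); all
"within" cutoffs (2.5, 4, 8, 1.5 Å) are inclusive (`≤`).

**Site score.** The score sums hot-spot ΔG over the best (most negative)
*connected* subset of at most 7 hot spots, where two hot spots connect
below the merge distance. The cap approximates the heavy-atom budget of
a drug-like fragment assembled from probe positions. This scoring is
this package's own convention for combining hot spots into a drug-like
footprint; it is exact (exhaustive over connected subsets, enumerated
once each) and deterministic.

**Binding scores.** For probe type *p* and residue *i*, s(p,i) = Σ 1/d²
over all frames and all heavy-atom pairs (residue atom, probe atom) with
d ≤ 4 Å. Multiple simultaneous contacts in one frame all count, so tight
multivalent contact scores superlinearly. Backbone atoms are included:
the residue's heavy atoms are taken as a whole. Scores are additive over
frame partitions and exactly linear in trajectory length. Residues with
s(p,i) strictly above 500 Å⁻² are called high-affinity; the 500 figure
is calibrated for runs of 10,000 stored frames over 40 ns, and scores
scale linearly with length, so shorter runs warrant a proportionally
smaller threshold — the package deliberately does *no* automatic
rescaling, exposing the threshold instead.

**Site selection.** A high-affinity call (residue, probe p) is kept when
any heavy atom of the residue, in *reference* coordinates, is within
8 Å of a hot-spot center of type p belonging to the analyzed site (site
geometry is defined in the reference frame, so reference coordinates are
the consistent choice). A probe with no hot spots at the site simply
contributes nothing.

**Interaction frequency.** A frame counts for a (residue, probe-type)
pair when some probe copy simultaneously (a) touches the residue —
heavy atom within 4 Å of a residue heavy atom — and (b) occupies a site
hot spot of its own type: *any* of its atoms, hydrogens included, within
1.5 Å of a hot-spot center. The heavy/any asymmetry between (a) and (b)
is intentional: contact is a heavy-atom notion, hot-spot assignment uses
the whole probe. A frame counts once per pair regardless of how many
copies qualify — snapshots are counted, not instances. Frequency is
count/n exactly. Records are ranked by frequency, ties broken by binding
score and then by (chain, residue, probe) so orderings are reproducible
across platforms; the top set keeps frequencies ≥ 0.10, inclusive.

**Snapshots and pharmacophores.** Frames in which *every* top-ranked
interaction holds are intersected, their conformational spread is
summarized as the mean pairwise Cα RMSD (no per-pair refitting —
conformers already share the reference frame), and each is exported as
a protein PDB plus a PDB of the qualifying probe copies. Each probe copy
contributes features per its spec's templates: a feature sphere of
radius 1 Å at a named heavy atom or at the centroid of a named subset.
Hydrophobic (and aromatic) features sit on centroids rather than a
specific carbon; donors/acceptors sit on the donor/acceptor atom itself.
The built-in templates are: isopropanol → donor(hydroxyl O) +
hydrophobic(C centroid); acetamide → donor(N) + acceptor(O); isobutane →
hydrophobic(C centroid); imidazole → aromatic(ring centroid) +
donor(ND1) + acceptor(NE2); acetate → negative(carboxylate centroid) +
acceptor(O); isopropylamine → positive(N) + donor(N). The charged and
aromatic templates are standard chemotype assignments chosen by this
package; feature subsets are selectable per run. One model is built per
co-occurrence snapshot — users are encouraged to screen all of them and
compare. Export is the Pharmit session format (a `points` array with
names `HydrogenDonor`, `HydrogenAcceptor`, `Hydrophobic`, `Aromatic`,
`NegativeIon`, `PositiveIon`); directional/vector features and exclusion
volumes are not emitted.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `edge_length` | 0.5 | Å | voxel size |
| `protein_contact_cutoff` | 2.5 | Å | probe counted at all |
| `merge_distance` | 5.5 | Å | voxel → hot spot (strict <) |
| `site_link_distance` | 5.5 | Å | hot spot → site (strict <) |
| `min_hotspots_per_site` | 6 | — | minimum cluster size |
| `hotspot_energy_cutoff` | −1.0 | kcal/mol | candidate voxel call |
| `max_combination_size` | 7 | — | site-score budget |
| `temperature` | 300 | K | RT in the Boltzmann inversion |
| `contact_cutoff` | 4.0 | Å | s(p,i) and criterion (a) |
| `score_threshold` | 500 | Å⁻² | high-affinity call (strict >) |
| `site_cutoff` | 8.0 | Å | residue-at-site selection |
| `hotspot_assign_cutoff` | 1.5 | Å | criterion (b) |
| `frequency_cutoff` | 0.10 | — | top set (inclusive ≥) |

## The synthetic-fixture generator

Validating a trajectory-analysis tool needs trajectories with known
answers. `generate_fixture()` builds a rigid toy fold — two ideal
α-helical poly-alanine chains (50 residues each by default, ≈500 atoms)
with small Gaussian backbone jitter (0.05 Å) — and plants binding events
whose ground truth is recorded in a manifest. A planted locus clusters
one copy of each configured probe type (all six by default) in a cone of
directions around a surface residue's Cβ, each copy's anchor atom placed
2.1 Å from the Cβ: firm contact, comfortably inside every cutoff, so
that small numerical residuals (PDB coordinate rounding, the Cα-fit
residual under backbone jitter) can never flip a frame across a distance
boundary. Six distinct probe types yield six per-type hot spots within
linkage distance — exactly one druggable site per locus at the default
parameters. Each copy is present at its locus in an independent
Bernoulli(f) subset of frames (default f = 0.48, the order of the
strongest interactions seen in real runs) and is otherwise placed in the
bulk. Bulk and unbound probes are resampled uniformly per frame in an
8–25 Å shell around the protein where they cannot register a protein
contact; they exercise the non-binding population without adding
occupancy signal. Planted copies may interpenetrate one another — only
occupancy statistics matter to the analysis, not probe–probe sterics —
and bulk motion has no dynamics. By default every frame additionally
receives a random rigid rotation and translation, emulating unaligned MD
output, which superposition must undo.

The manifest's expected outcomes (bound-frame sets, expected hot-spot
centers, qualifying-frame sets, full per-residue binding-score profiles)
are computed inside the generator by plain, independent loops over the
generated coordinates — never by the pipeline modules — so
manifest-versus-pipeline comparisons in the tests are genuine oracle
tests. What the fixtures do **not** emulate: real side-chain chemistry
and flexibility, water, probe–probe competition, diffusive kinetics,
periodic boundaries. Passing tests therefore demonstrate the
correctness of the *statistics and geometry* of the analysis, not the
biophysical fidelity of any particular MD setup.

## Numerical choices and degenerate inputs

* Ties in the greedy voxel merge are broken lexicographically; ties in
  site ranking by cluster label; ties in interaction ranking by the
  three-level key above. Identical inputs give byte-identical outputs
  (all writers use fixed formats and `\n` endings).
* A zero-count voxel has ΔG = +∞; an empty candidate set yields an empty
  hot-spot list, and a run with no sites exits with a distinct
  `"no-sites"` status rather than an error.
* The first alternate location of a PDB atom is kept; insertion codes
  are part of residue identity; chains are never pooled.
* DCD files are read (via bio3d) and written in plain CHARMM format
  without unit-cell blocks; coordinates round-trip at single precision
  (~1e-4 Å), PDB coordinates at 1e-3 Å.
* Pharmit JSON round-trips coordinates at full double precision
  (~1e-15 relative, the decimal round-trip limit).

## Problem sizes used in the tests

The shipped validation runs on desk-scale versions of the study
conditions: 50–400-frame fixtures for oracle equivalence and workflow
checks, twenty 120-frame fixtures with one to three planted loci for
recovery statistics, and one 2,000-frame fixture for frequency
estimation (planted f = 0.3, recovered within binomial 3σ) and
high-affinity calling (a sustained locus clears the length-scaled
threshold; all other residues score 0). Real 40 ns / 10,000-frame
trajectories process the same way, only longer.

## Known limitations

* The site score is a documented stand-in for proprietary "drug-like
  combination" scoring used by some druggability tools; ranks agree in
  spirit (more, deeper, denser hot spots score better) but not
  necessarily numerically with any other package.
* Occupancy-based ΔG values are enrichment free energies against a
  uniform accessible background; they are comparable across sites of
  one run, not calibrated absolute binding free energies.
* No periodic-image handling: trajectories must be pre-wrapped.
* Pharmacophore export covers point features only — no shape
  constraints, exclusion volumes or feature vectors.

## A worked run

```{r, eval = FALSE}
fx <- generate_fixture(fixture_config(n_frames = 400,
                                      loci = list(list(f = 0.8))),
                       seed = 73, dir = "fixture")
res <- run_pipeline(run_config("fixture/reference.pdb",
                               "fixture/trajectory.pdb",
                               out_dir = "out",
                               score_threshold = 500 * 400 / 10000))
res$sites$sites          # ranked druggable sites
res$ranking$table        # frequency-ranked interactions
length(res$frames)       # co-occurrence snapshots
res$mean_conformer_rmsd  # conformational spread of those snapshots
```

The same workflow is available from a shell via the thin CLI installed
at `system.file("cli", "probemap", package = "probemap")`, with
subcommands `make-fixture`, `hotspots`, `profile`, `siteselect`,
`rank`, `snapshots`, `pharmacophore` and `run-all` (exit codes: 0
success, 2 no sites, 1 error).
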