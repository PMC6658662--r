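---
title: "Models, estimators and design choices in hyperbar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in hyperbar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperbar)
```

`hyperbar` analyses molecular-dynamics trajectories of a tetrameric ion
channel embedded in a phospholipid bilayer, with the specific goal of
comparing matched runs: a control at ambient pressure, the same system
under hydrostatic pressure, and the same system saturated with a
dissolved monatomic gas. This vignette explains the models behind each
estimator, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices that were
genuinely open.

## Units, formats and the data model

The internal length unit is nm everywhere; Angstrom appears only at the
PDB boundary and in printed site/gate distances, following the
conventions of the source formats (GRO stores nm, PDB stores Angstrom).
Only rectangular boxes are supported: the GRO box line's first three
fields are read as edge lengths and nonzero triclinic components are
rejected outright rather than silently truncated. Atom serials are
1-based both in files and in memory — R indexes from 1, so the usual
convention of converting to 0-based indices at the file boundary would
only add a failure mode.

A `topology` carries per-atom name, residue, chain, element, mass and
van der Waals radius. Elements, masses and radii are inferred from atom
names against a small bundled table (H, C, N, O, P, S, the noble gases
and common ions) with per-atom overrides; unknown names fall back to
carbon-like values with a warning, because dying on an exotic atom name
in an otherwise valid file helps nobody. Radii matter only to the
volumetric and pore estimators.

## Periodic-boundary cleanup

The three transforms mirror the canonical trjconv sequence. `make_whole`
anchors each molecule at its lowest-index atom and walks the bond graph
breadth-first, shifting every neighbour by the lattice vector that
minimises the bond length; the anchor and traversal order are fixed to
make the output deterministic (the reference tools do not document
theirs). `center_group` uses the geometric (unweighted) group mean,
matching the default of the reference tool. `compact_pack` searches only
the 27 nearest images, sufficient for rectangular cells with molecules
smaller than the box. All three preserve image-minimum pairwise
distances, which the test suite asserts directly.

## RMSD and conformational clustering

Superposition uses the standard Kabsch construction on the weighted
cross-covariance SVD, with the reflection corrected so the returned
rotation is always proper. Degenerate (collinear) point sets fall back
to whatever proper rotation the LAPACK SVD ordering produces — a
documented, deterministic tie-break. The clustering is the greedy
neighbour-counting (gromos/Daura) algorithm at a cutoff of 0.5 nm over
pairwise superposition RMSDs of the protein selection, run on the final
50% of frames; both cutoff and window are parameters. Two conventions
are pinned down because the reference implementation leaves them open:
ties in neighbour count go to the lowest frame index, and clusters are
reported by descending size with a stable order. Printed probabilities
round half away from zero (banker's rounding would print 0.825 as 0.82
where run tables print 0.83); full precision is kept internally. The
reported "number of clusters" includes the largest cluster — run tables
that speak of "N smaller clusters" are off by one from this count, which
is why the summary always reports total frames and sizes alongside.

## Density profiles and RDF layouts

The Z-density histogram accumulates atomic masses into bins of the
wrapped z coordinate in absolute box coordinates and converts to
kg m⁻³ with the slab volume; mass conservation (sum over bins times slab
volume equals the group mass) is asserted to 1e-6 relative in the tests.

The radial distribution function g(r) uses image-minimum distances and
the textbook normalisation by 4πr²Δr times the target number density.
The per-residue "layout" machinery summarises solvation along a protein
chain: every 5th C-alpha (starting from the first resolved residue)
serves as a single-atom reference, one RDF is computed per sampling
window, g is averaged over r in 0–3.4 nm — an unweighted mean over bins,
the plain reading of "averaged over the range"; a shell-weighted mean is
a keystroke away but is not the default — and the across-window mean and
standard error (n−1 denominator) are reported per residue. Windowing is
a (start, width, gap) triple; the classic choice of 5 ns windows
separated by 10 ns gaps over the second half of a 100 ns run yields four
windows, and `synth_windows()` reproduces the same structure on
synthetic trajectories.

Two bulk-density conventions are supported for the normalisation of
g(r). The default, "box", divides by the whole-box target count — the
simplest convention and the one a generic RDF tool applies. For
condition-to-control comparisons the package also offers "slab", which
estimates the bulk density from a membrane-free z sub-region: with a
fixed reference region the condition/control ratio of layout values
reflects local (de)hydration only, rather than being convolved with
global count differences between the runs. The pipeline and the
parameter-recovery suite use "slab" for exactly that reason; the ratio
of a fully dehydrated shell then has expectation exactly
1 − dehydration.

Adjacent layout rows are not independent: references 5 residues apart
sit a few Angstrom from each other while the averaging sphere has radius
3.4 nm, so neighbouring rows share almost all of their sample. Pooled
statements over rows therefore use the propagated per-window standard
error, never the across-row scatter.

## Acyl-chain order parameters

United-atom force fields carry no aliphatic hydrogens, so the two
geminal hydrogens of each sp³ chain carbon are reconstructed from the
local carbon geometry: the C–H unit vectors are symmetric about the
exterior bisector of the two C–C bonds, separated by the ideal
tetrahedral H–C–H angle, in the plane spanned by the bisector and the
normal of the C–C–C plane. The C–H length is fixed at 0.109 nm; it
cancels from S_ch, which uses direction only. The prochiral labels
follow the package's own convention — pro-R is the hydrogen with
positive scalar triple product det(c_prev−c, c_next−c, H−c) — and the
mirror-swap property (reflecting the system through a plane containing
the normal exchanges the pro-R and pro-S columns exactly) guarantees the
two curves are consistently separated regardless of which absolute label
convention a reference tool used. sp² carbons (the C9=C10 double bond)
receive a single in-plane hydrogen on the exterior bisector, so the two
prochiral curves coincide there by construction. Terminal carbons lack a
neighbour and are excluded, matching the conventional C2–C17 plotted
span. S_ch is always reported signed; report layers may negate it for
display. Standard errors are computed across lipids, each lipid
contributing its frame-averaged profile.

## Rolling-probe volumes

The solvent-excluded volume is computed on a voxel grid: atoms are
inflated by the probe radius, the exterior is flood-filled from the grid
boundary with 6-connectivity, the non-exterior region is eroded back by
the probe radius, and the eroded voxels are united with the vdW-occupied
ones. The erosion uses the continuous clearance of each near-surface
exterior voxel (its distance to the nearest inflated atom surface) to
correct for lattice offsets; without this the erosion radius is biased
by about half a voxel, which at a 1.4 Å probe and 0.2 Å grid is a
10–15% volume error on a single atom — with it, the single-sphere volume
is recovered to well under 1%. Defaults: probe 0.14 nm and grid 0.05 nm
for molecular groups, probe 0.6 nm and grid 0.1 nm for the continuous
gas phase between the leaflets, whose bounds default to the two
phosphate-peak positions of the density profile. Gas atoms are gridded
with a 0.14 nm radius (half the helium Lennard-Jones σ of 0.256 nm,
rounded up to the tabulated value). Only atoms of the named group block
the probe; ions and water are not implicit blockers. Percent changes
against the control run are 100·(V − V₀)/V₀, printed after rounding half
away from zero to two decimals.

## Pore, site and gate geometry

The pore profile replaces a full Voronoi/Delaunay tunnel search with
slice-wise maximal inscribed circles along the Z axis, which is adequate
once the channel has been centered and is testable against closed forms
(a cylinder of wall atoms with radius R and atom radius r profiles at
exactly R − r). Each slice maximises the clearance
min over atoms of (3D distance − vdW) by a coarse grid search refined
with bounded quasi-Newton iterations; after the first slice the center
may move at most 0.25 nm per 0.1 nm slice, which prevents the search
from escaping sideways through gaps between discrete wall atoms at
constrictions. The surface is sampled at 36 azimuthal points per slice
and the reported extents are bounding-box lengths of that cloud — the
measurement protocol for "extent" statements is otherwise undefined.

The binding-site geometry projects the four selected side-chain oxygens
onto the XY plane and orders the vertices by polar angle about their
centroid, which makes "sides" and "diagonals" well defined whatever the
input order; distances are reported in Angstrom. The gate metric is the
C-alpha pair distance of a marker residue on the two opposite subunits,
labelled open when ≥ 28 Å — a threshold placed between published open
(≈ 33.6 Å) and closed (≈ 23.4 Å) reference values, configurable, and
always reported alongside the raw distance. Helix comparisons are
superposition RMSDs only; no secondary-structure assignment is
attempted.

## The synthetic generator

`build_system()` is a statistical emulator, not an MD engine, and the
distinction matters: frames are independent redraws of a stationary
ensemble. Every analysis in the package estimates a time average of a
stationary observable, so temporal correlation structure would add cost
without adding a test; but it also means passing parameter-recovery
tests says nothing about kinetics, barostats, or any time-correlated
feature of real trajectories, and the sampling-window machinery's
"gaps" are physically meaningful only on real data.

What it builds, and the corresponding ground truth:

* **Bilayer** — lipids on two leaflet lattices, each with a phosphate
  bead and two 18-carbon zig-zag tails grown with ideal geometry
  (0.153 nm bonds, 111° angles). The chain axis tilt β from the normal
  is chosen from the target order parameter via
  ⟨cos²θ⟩ = sin²β/2, i.e. S = (3 sin²β/2 − 1)/2, with the tail azimuth
  and zig-zag plane drawn uniformly per lipid and frame; the
  reconstructed C–H vectors then have analytic expectation S at every
  carbon. Reachable targets are −0.5 < S ≤ 0.25; the default 0.20 is a
  typical mid-chain value for an ordered bilayer. A target of 0.20
  corresponds to a 75° tilt — the generator trades geometric realism for
  an exact, testable expectation.
* **Channel** — four chains (A–D) of C-alpha beads. The transmembrane
  block (40% of residues) lines the analytic pore surface at
  radius r(z) + 0.17 nm with golden-angle azimuths for even coverage;
  the rest rise through the extracellular region. Labelled
  pseudo-residues make the standard selectors resolve: a gate marker
  (residue 299, chains A/C) at a prescribed separation, and four
  site oxygens (OD1 of residue 606 on A/C and 598 on B/D) at
  configurable quadrilateral corners. Protein beads get small Gaussian
  per-frame jitter (0.02 nm).
* **Water** — uniform beads, thinned with probability `dehydration`
  inside a cylindrical shell around the transmembrane domain. The shell
  is sized so that the whole 3.4 nm averaging sphere of every
  transmembrane reference lies inside it, making the layout-ratio truth
  exactly 1 − dehydration under slab normalisation.
* **Gas** — each atom goes to the inter-leaflet slab with probability
  `f_gap` (otherwise uniform in the box), under a hard-core exclusion of
  0.256 nm enforced with image-minimum distances; placement failure
  after 200 retries per atom is a packing error, not a silent
  degradation. Because bulk gas also passes through the gap, the
  expected observed slab fraction is
  f_gap + (1 − f_gap)·(gap width / box height); `ground_truth()` reports
  it.

The default spec (10 × 10 × 20 nm box, 128 lipids, 5000 waters, 2000 gas
atoms at f_gap = 0.9, 20 frames 2 ps apart) is sized so the full
parameter-recovery suite runs in minutes on one CPU; these are the
package's reference study conditions, stated here once and not tuned per
test. Identical spec and seed produce byte-identical trajectories — the
generator seeds the global RNG from `spec$seed`.

## What the tests do and do not show

The suite establishes: exact worked-example arithmetic on published
cluster and volume tables; exact agreement of the clustering with a
naive greedy oracle and of the RDF with an all-pairs histogram oracle;
Kabsch RMSD within 1e-3 nm of a rotation-grid search; closed-form
order-parameter limits (1, 0, −0.5) and volumetric/pore limits; and
recovery of generator ground truth (order 0.20, dehydration ratio,
gas partitioning, slab volume, pinched-pore radius) within the stated
statistical bounds. It does not — cannot — reproduce the headline
numbers of any specific published simulation study: those depend on
~100 ns all-atom trajectories that were never deposited. The package's
claim is that, given such trajectories, every stage of the published
analysis chain can be rerun with tested, deterministic code.

## Known limitations

Triclinic cells, velocities and TPR topologies are out of scope, as are
force fields and integrators. The pore profiler assumes an axis-aligned,
unbranched channel. Lipids in the generator overlap sterically (no
excluded volume between molecules) — irrelevant to the estimators under
test, but visually unphysical. The XTC binary format is not read; GRO
carries the same coordinates at fixed precision.
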