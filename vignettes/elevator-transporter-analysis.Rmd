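---
title: "Methods: quantitative structural analysis of elevator-type anion transporters"
author: "elevatorStruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative structural analysis of elevator-type anion transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevatorStruct)
```

# Scope and model system

SLC26A2 is an SO~4~^2−^/Cl^−^/oxalate exchanger of the SLC26 family whose
transmembrane domain (TMD, 14 helices in the UraA fold) splits into a core
sub-domain (TMs 1–4, 8–11) and a gate sub-domain (TMs 5–7, 12–14). The core
slides vertically against the gate — the elevator mechanism — alternating
access of the TM3/TM10 substrate pocket between the two membrane sides.
This package implements the downstream quantitative analyses such a
structure/simulation study needs: residency statistics from binding
trajectories, pore geometry and the open/closed call, interface areas and
contacts, map–model Q-scores, membrane-slab placement and structure-based
missense variant categorisation. Cryo-EM reconstruction, model refinement
and force-field MD are out of scope; the package starts where those
pipelines end (coordinates, maps, distance traces).

# Residency statistics

A trajectory is reduced to one scalar per frame: the distance from the
substrate (atom or centroid) to a reference atom, by default the Cα of the
residue at the N-terminal end of TM3 (G166 in SLC26A2). The bound criterion
is a closed window, default 3.5–8 Å. Design choices worth stating:

* **Window inclusivity.** The window is described in the literature only as
  "between 3.5 and 8 Å"; we adopt the closed interval and expose it in
  `bindingWindow()`. The synthetic generator's emissions deliberately avoid
  the edges (bound 4.0–7.5 Å, unbound 9–30 Å) so that no synthetic result
  can depend on the inclusivity convention; edge behaviour is tested with
  explicit fixtures at exactly 3.5 and 8.0 Å.
* **Reference atom.** Only "the end of TM3" is specified upstream; whether
  the original distance was to Cα, backbone or any atom of G166 is unknown.
  The Cα default is configurable per run and recorded in reports.
* **Error bars.** Replicate aggregation uses the sample SD over replicate
  fractions (n−1), matching the way 3-replicate MD occupancies are quoted;
  no autocorrelation-corrected errors are attempted. Single replicates are
  flagged and report SD 0.
* **Frame time is abstract.** All statistics are per-frame fractions; the
  1 µs / frame-stride scale of real trajectories is not modelled.

The synthetic generator is a two-state Markov chain (per-frame transition
probabilities `p_on`, `p_off`) with uniform distance emissions per state.
Its presets encode the stationary occupancies of the three substrates:
chloride `p_on = 0.0041, p_off = 0.0009` (stationary 0.82), sulfate
absorbing-bound (1.0), oxalate `p_on = 0.00325, p_off = 0.00175` (0.65).
The chain starts from its stationary distribution (sulfate: bound), so the
estimator is unbiased at any length; at the 3 × 100,000-frame design the
Monte-Carlo SE of the replicate mean is ≈ 1.4 percentage points
(autocorrelation time 1/(p_on+p_off) = 200 frames). The generator
reproduces the replicate *mean*; the inter-replicate spread of real MD
(± 4 points) arises from slow conformational variability the two-state
model does not contain — tests therefore target the mean only.

# Pore geometry and the open/closed rule

Pore radii are exact distances-to-vdW-surface along a sampled path:
`r(p) = max(0, min_a(‖p − x_a‖ − r_vdW(a)))`. The default path is a
straight axis between two anchors sampled every 0.5 Å — a deliberate
simplification of curved-channel searches (MOLE/HOLE-style), adequate for
the axial toy systems and for the open/closed rule, but *not* expected to
reproduce curved-pathway radii on deposited structures; only the
qualitative open/closed agreement is a testable claim there. A side is open
when every radius between the pocket and that terminus strictly exceeds
1.8 Å (the unhydrated Cl⁻ radius); equality counts as closed. The
brute-force O(points × atoms) scan is the reference; a cell-list
accelerator with a provable pruning bound must (and is tested to) match it
exactly.

Radii come from a Bondi-style element table (default carbon fallback
1.7 Å, logged); the radii/altloc conventions behind published
graphics-program measurements are not stated anywhere, so both are
configurable and recorded. Altlocs resolve to the highest-occupancy
conformer (ties: alphabetical), hydrogens are not required, author residue
numbering is preserved throughout, and map origins are honoured from the
header with no implicit re-centering.

# Interfaces

SASA is Shrake–Rupley with a deterministic generalized-spiral point set
(default 960 points, probe 1.4 Å) — no RNG, so areas are exactly
reproducible; the discretisation scale is ~2% of an atom's expanded-sphere
area, which is also the tolerance used in the convergence test. Buried area
follows the `(A + B − AB)/2` convention, computed **with only the union's
atoms present**: a group's isolated SASA is its SASA extracted from the
assembly, not in the context of remaining chains. This matters numerically
and is stated in every report. Hydrogen-bond detection on hydrogen-free
cryo-EM models is heavy-atom distance with N/O typing (2.0–3.5 Å default),
flagged `distance`-mode; reported bond lengths are heavy-atom distances.
When hydrogens exist, a ≥120° angle at the hydrogen is additionally
required. Cation-π pairs are ring-centroid to cation-centre distances
≤ 6 Å.

# Map–model Q-score

Per atom, the map is sampled (trilinear) at the centre and on concentric
shells (0.1–2.0 Å in 0.1 Å steps, 8–32 deterministic spiral points per
shell); points nearer to any *other* model atom are discarded; the Q-value
is the Pearson correlation with a reference Gaussian of width 0.6 Å — the
published convention; the width is configurable and always logged.
Correlation is invariant to positive affine maps of the density, so no
amplitude fitting is needed. Numerical edge cases: flat (zero-variance)
samples return Q = 0 with a flag rather than an error, detected with a
relative spread threshold because trilinear interpolation of a constant
grid leaves ~10⁻¹⁶ jitter; atoms outside the map are excluded with a
warning. Self-agreement of a structure with its own rendered Gaussian map
is the hard oracle (≥ 0.99 for an isolated ligand at voxel ≤ 0.4 Å); in
dense atom packings, neighbour density at the far shells caps self-Q near
0.99 even for a perfect model — a property of the single-Gaussian
reference, worth knowing when reading per-residue scores.

# Membrane slab and variant categories

The slab stands in for PPM-style membrane positioning. The normal is fixed
to the first principal axis of the Cα cloud (TM helices run along the
normal, so this axis dominates); centre offset and half-thickness (10–25 Å)
are grid-searched at 0.5 Å steps maximising Σ hydropathy of exposed
residues inside the slab minus Σ outside. This was chosen over a full
orientation search because the downstream features need only boundary
proximity, and determinism matters more than PPM parity here. One subtlety:
for a structure with *no* hydrophobic belt the objective is maximised by
covering as little hydropathy mass as possible and can still be positive,
so the confidence flag is floored on the *inside* hydropathy sum
(`low_confidence` when ≤ 0) rather than on the objective itself.

Variant categories are assigned by ordered rules (substrate site → lipid
interface → fold → unexplained) over the residue environment and
substitution deltas from fixed published tables (Kyte–Doolittle hydropathy,
formal charge at pH 7, residue volumes). The thresholds — pocket 8 Å,
boundary 5 Å, relative accessibility 0.2, hydropathy −3, volume +25 Å³ —
are calibration parameters of this package, set once so the curated
25-variant fixture reproduces its reported mechanistic reading, and are
part of the config contract, not measured quantities. Two rule details:

* The lipid rule accepts a hydropathy drop, *any* charge change, **or a
  proline introduction** at a lipid-facing boundary position. Without the
  proline clause, boundary mutations like S157P/Q454P (hydropathy deltas
  −0.8/+1.9, no charge change) cannot reach the lipid category their
  structural context demands; helix-breaking at the bilayer boundary is a
  lipid-contact defect, so the clause belongs there.
* `helix_context` flags *regular secondary structure* (helix or strand):
  glycine is destabilising in both, which is what routes a β-strand
  mutation like C653G into the fold category. Loss of a side chain engaged
  in ≥ 2 hydrogen bonds (e.g. N425D) adds a fold vote, fed from the H-bond
  census on the reference structure or curated directly.

The curated fixture encodes, for each of the 25 ClinVar missense variants
(21 residues), hand-assigned environment features reflecting its published
structural context; it is annotation, not measurement, and is labelled as
such. The classifier reproduces the reported category for all 25,
including D250V as `unexplained` — an exposed cytosolic-entry aspartate
whose pathogenicity the structural logic cannot explain. The
charged-entry census (ARG/LYS/HIS positive, ASP/GLU negative, side-chain
centroid within 12 Å) replaces full Poisson–Boltzmann electrostatics by
design.

# Synthetic data: what it does and does not show

`buildToyBundle()` produces ideal α-helices (rise 1.5 Å, twist
100°/residue, Cα radius 2.3 Å) on a ring about z, with a pseudo-CB 1.5 Å
further from the helix axis, hydrophobic identities inside the |z| ≤ 15 Å
belt and polar outside. The ring default (5.5 Å + cleft radius) makes the
innermost atom surfaces graze a cylinder of exactly the requested cleft
radius, giving the pore stage a constructed ground truth; helix phases are
staggered so inward side chains sample the pore wall densely. The bundle
emulates the features the analyses rely on — an axial cleft, a hydrophobic
belt, lipid-facing vs cleft-facing side chains — and none of the rest of
real membrane proteins: no loops, no backbone carbonyls, no lipids, no
waters, no B-factors. Green tests on synthetic data therefore demonstrate
*estimator and geometry correctness under the stated model*, not agreement
with deposited structures; the deposited-data checks exist separately and
require the user to supply the files.

# Problem sizes and determinism

Default test and demo sizes — 3 × 100,000-frame traces, 360-atom bundles,
0.3–0.5 Å voxel maps of ligand-scale structures, 240–960 SASA points —
were chosen so every stage's statistical tolerance is comfortably met while
a full run stays interactive on a single CPU. Every stochastic component
takes an explicit seed and restores the caller's RNG state; same config and
seed means byte-identical reports, which the pipeline's manifest (config
hash + per-file md5) makes checkable.

# Known limitations

Straight-axis pore paths (no curved-channel optimisation); distance-only
H-bonds on hydrogen-free models; no ΔΔG or conservation features in variant
annotation (structural-context logic only); no kinetic rate estimation from
traces; the two-state generator reproduces stationary occupancies, not
kinetics or replicate spread; mode-2 MRC only; first model only for
multi-model files.
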