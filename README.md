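# elevatorStruct

Quantitative structural analysis of elevator-type anion transporters of the
SLC26 family, built around the cryo-EM structures of SLC26A2 — the
sulfate/chloride/oxalate exchanger whose missense mutations cause a spectrum
of chondrodysplasias. The package is aimed at structural biologists and
computational biophysicists who want the downstream numbers of such a study
— substrate residencies, pore geometry, interface areas, map–model
agreement, variant classifications — as reproducible, testable code rather
than one-off measurements in a graphics program.

## What it computes

**Substrate residency from distance traces.** MD trajectories are reduced to
a scalar per frame: the distance *d* from the substrate to the Cα at the
N-terminal end of TM3 (G166). A frame is *bound* when

    3.5 Å ≤ d ≤ 8 Å          (closed window; configurable)

and the residency statistic over R replicates is the mean ± sample SD
(n−1) of per-replicate bound fractions. A 6–8 Å sub-window measures how
often a chloride ion intersects the sulfate site. A built-in two-state
Markov generator (per-frame transition probabilities `p_on`, `p_off`;
stationary bound probability `p_on/(p_on+p_off)`) provides synthetic traces
whose presets encode the residencies of the three substrates: chloride
(0.82), sulfate (absorbing, 1.0) and oxalate (0.65).

**Translocation-pore geometry.** Along a sampled path, the pore radius at
point *p* is the largest sphere that does not penetrate any van der Waals
sphere,

    r(p) = max(0, min_a (‖p − x_a‖ − r_vdW(a))),

and a membrane side is *open* when every radius between the substrate
pocket and that terminus is strictly larger than 1.8 Å, the radius of an
unhydrated Cl⁻ ion. Cleft widths (Cα pairs 165/442, 166/441, 167/440),
elevator displacement after gate-domain superposition, ligand-neighbour
censuses, ligand site displacements, and Cα RMSD via the Kabsch algorithm
round out the geometry stage.

**Interfaces.** Shrake–Rupley SASA with deterministic spiral points; buried
area between groups A and B as `(SASA_A + SASA_B − SASA_AB)/2`; geometric
hydrogen-bond and cation-π detection.

**Map–model quality.** Per-atom Q-score: the correlation between map values
sampled on concentric shells around an atom (points nearer to other atoms
discarded) and a reference Gaussian of width 0.6 Å. 1 means ideal
agreement; ~0.6 is typical at 3–3.5 Å resolution.

**Variant annotation.** A membrane slab is placed by maximising a
hydropathy objective over slab centre and half-thickness (normal from the
principal axis of the Cα cloud); each missense variant is assigned, by
ordered rules over its structural environment and substitution deltas
(Kyte–Doolittle hydropathy, formal charge, residue volume), to
`substrate_site`, `lipid_interface`, `fold_destabilizing` or `unexplained`.
A curated 25-variant ClinVar fixture ships with the package.

## Worked example

```r
library(elevatorStruct)

# synthetic chloride residency, 3 replicates
traces <- lapply(1:3, function(s)
    simulateBindingTrace(kineticPresets("cl"), 100000, seed = s))
aggregateReplicates(traces)
#> Residency over 3 replicate(s): 84% +/- 0%
#>   per replicate: seed1=0.840, seed2=0.841, seed3=0.847

# pore profile of a toy bundle with a 2.5 A axial cleft
s  <- buildToyBundle(bundleSpec(cleft_radius = 2.5, seed = 1))
pp <- poreProfile(s, porePath(c(0, 0, -21), c(0, 0, 21)))
pp$min_radius
#> [1] 2.507434

# variant classification on the curated ClinVar fixture
ann <- annotateVariants(curatedVariantTable())
table(ann$category)
#> fold_destabilizing    lipid_interface     substrate_site        unexplained
#>                 14                  8                  2                  1
```

The residency print-out mirrors how replicate MD occupancies are quoted
(integer percent with replicate spread); the pore minimum radius recovers
the radius the toy bundle was built with; and the category table matches
the mechanistic reading of the 25 ClinVar missense variants — 14 destabilise
the fold, 8 perturb lipid interactions, 2 sit at the substrate site, and
D250V remains unexplained.

An end-to-end run (bundle → traces → pore → variants, with manifest and
logs) is one call:

```r
runPipeline(demoConfig(outdir = "demo_run", seed = 1))
```

or from a shell, `Rscript inst/scripts/pipeline.R --demo --outdir demo_run`.

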