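# isletmorph

3D morphometry of cleared, light-sheet-imaged pancreatic islets, with a
fully ground-truthed synthetic phantom generator.

Whole-mount immunofluorescence of optically cleared islets, imaged by
light-sheet microscopy, shows how hypoxia reorganises the islet: under
1% O₂ the extracellular matrix condenses into a central scar with scarce
nuclei, laminin collapses from many small scattered nodes into one or
two large condensations, E-cadherin develops enclosed central signal
voids ("holes") and a higher mean intensity, and a CA9-positive rim
marks the hypoxic zone around the necrotic core. This package implements
the digital image analysis for that phenotype and the statistics used to
compare culture conditions, and — because deposited microscopy data is
not needed to verify an algorithm — a seeded phantom generator that
emulates the normoxic (ND1, ND5) and hypoxic (HD5) morphologies with
exact ground truth.

## What it computes

For a multi-channel 3D stack `I(c, z, y, x)` with voxel size
`(dz, dy, dx)` µm:

* **Islet delineation** — threshold the Gaussian-smoothed sum
  `G_σ(Σ_c I_c)`, fill internal cavities, label 26-connected components,
  drop debris below a minimum volume; watershed on the anisotropic
  Euclidean distance transform splits touching islets.
* **Stain detection** — per marker: `G_σ(I_c) > t` (absolute) or
  `max(G_σ(I_c) − G_Σ(I_c), 0) > t` (background-subtracted, `Σ ≫ σ`);
  no morphological post-processing.
* **Morphometry per islet** — volume `|Ω|·dz·dy·dx`; stained volume
  fraction `100·|S ∩ Ω| / |Ω|`; laminin node count and volumes
  (26-connected components above a minimum volume); E-cadherin hole
  fraction (enclosed unstained components, excluding any that touch the
  boundary shell); raw mean intensity; CA9 fraction.
* **Viability** — on 2D live/dead images, `|G| / |G ∪ R|` (green =
  fluorescein/viable, red = propidium iodide/dead).
* **Statistics** — Shapiro–Wilk screening with optional natural-log
  transform, Welch (or pooled) two-by-two t tests, one-way ANOVA,
  Pearson correlation; means ± SD always reported on untransformed data.

## Worked example

The `analysis/` scripts run the full study on synthetic cohorts
(8 islets per condition, seed-paired so the three groups have identical
size distributions). Step 2 prints, for seed 1:

```
Measured 72 islet x marker records from 24 stacks; 0 failures.
ND1: nodes 7.25 +/- 1.16 | hole % 1.62 +/- 1.70 | E-cad AU 7885 | CA9 % 0.01
ND5: nodes 7.25 +/- 1.16 | hole % 2.15 +/- 1.20 | E-cad AU 5906 | CA9 % 0.02
HD5: nodes 1.62 +/- 0.52 | hole % 6.51 +/- 4.67 | E-cad AU 13056 | CA9 % 9.95
```

Each line is the pipeline's measurement (not the planted value): hypoxic
islets have few laminin nodes, larger hole fractions, brighter
E-cadherin and a substantial CA9-positive fraction, while the normoxia
groups stay near their planted baselines. Step 3 runs the statistics:

```
  laminin node count           HD5 1.62 +/- 0.52 vs ND5 7.25 +/- 1.16, t = -12.48, p = 2.82e-07 (none)
  E-cadherin hole fraction     HD5 6.51 +/- 4.67 vs ND5 2.15 +/- 1.20, t = 2.56, p = 0.0338 (none)
  E-cadherin mean intensity    HD5 13056.05 +/- 2350.09 vs ND5 5906.11 +/- 668.87, t = 8.28, p = 3.11e-05 (none)
  CA9 volume fraction          HD5 9.95 +/- 3.70 vs ND5 0.02 +/- 0.02, t = 20.17, p = 1.28e-09 (log)

ANOVA, islet volume ~ condition: F = 0.000, p = 1.000
```

The near-zero volume F is the built-in null: the groups are
size-matched by construction, so any rejection would indicate a
condition-dependent bias in the delineation itself. The trailing flag
on each comparison records whether the normality screen triggered the
log transform for that test.

Equivalent calls in code:

```r
library(isletmorph)
cfg <- phantom_study_config(seed = 1)
coh <- generate_cohort("HD5", 8, seed = 1)
report <- run_pipeline(cfg, cohort_inputs(coh, "HD5"))
head(report$records)
```

For real acquisitions, export stacks to multi-page TIFF, describe the
channels with `channel_map()`, list stacks and condition labels in a
manifest data frame, and pass both to `run_pipeline()` with a config
(`load_config()`) holding your protocol's per-marker thresholds. Every
run writes its resolved configuration next to its outputs.

## Layout

```
R/                  package code: imageio, phantom, segmentation,
                    morphometry, stats, pipeline
src/                Rcpp kernels: 3D labeling, border flood, exact
                    anisotropic EDT, marker watershed
analysis/           the study as numbered scripts (simulate, measure,
                    group statistics, figures) writing under results/
scripts/acceptance.R   headline-quantity recomputation (above)
vignettes/          methods vignette: model, parameters, phantom design,
                    numerical choices, limitations
tests/testthat/     unit, property and acceptance tests with
                    independent brute-force oracles
```
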