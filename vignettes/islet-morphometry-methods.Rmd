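---
title: "Methods: 3D morphometry of cleared islets and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of cleared islets and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmorph)
```

## The problem

Pancreatic islets (diameter 50–250 µm) cultured under hypoxia develop a
characteristic 3D phenotype visible in cleared, light-sheet-imaged
whole-mount immunofluorescence: extracellular-matrix proteins condense
into a central scar with scarce nuclei, laminin shifts from many small
scattered nodes to one or two large central condensations, E-cadherin
develops central signal voids ("holes") and an elevated mean intensity,
and a CA9-positive rim marks the hypoxic zone around the necrotic core.
`isletmorph` implements the digital image analysis for this phenotype —
islet delineation, per-protein volumetric quantification, node and hole
morphometry, 2D live/dead viability — together with the group statistics
used to compare culture conditions, and a synthetic phantom generator
that makes every stage verifiable without microscopy data.

## The measurement model

**Islet delineation.** The pixel values of all channels are summed,
smoothed with a Gaussian blur of physical width `sigma_islet` (default
3 µm), and thresholded; internal cavities are filled (a necrotic core
belongs to the islet volume), 26-connected components are labelled,
components below `min_islet_volume` (default the volume of a 20 µm-radius
sphere) are discarded as debris, and labels are ordered by decreasing
volume. All physical lengths are converted to voxels per axis, so
anisotropic sampling (coarser z, typical for light-sheet stacks) is
handled transparently. When no threshold is configured, Otsu's method on
the smoothed sum supplies one; because Otsu lands between the two
intensity populations, the resulting surface sits near the half-maximum
crossing of the smoothed edge, which for a blurred step edge coincides
with the true boundary. This matters for cross-condition comparability:
a *fixed* absolute threshold would place the surface of a brightly
stained hypoxic islet further out than that of a dimmer normoxic one,
creating a spurious volume difference.

**Touching islets.** Thresholded components can fuse islets that
coexist in one acquisition. Each labelled object is examined with a
Euclidean distance transform (anisotropic, exact); connected plateaus of
the smoothed distance map above `marker_fraction` (default 0.6) of the
per-object maximum become markers, and if two or more emerge the object
is flooded from them (priority-queue watershed on the distance map). A
split is accepted only when every part exceeds `min_islet_volume`;
otherwise the object is kept whole. The fraction-of-maximum marker rule
is a plateau-robust stand-in for local maxima detection; its known
limitation is that a small islet touching a much larger one (radius
ratio below `marker_fraction`) will not seed a marker and the pair stays
merged — the config exclusion list is the escape hatch, mirroring how
manual curation is replaced by recorded, reproducible decisions.

**Stain detection.** Per marker: Gaussian filter of width `sigma`; in
`background_subtracted` mode a copy blurred with `background_sigma`
(default 20 µm, necessarily larger than `sigma`) is subtracted with negatives
clamped, removing slowly varying background while preserving blob
contrast; then a single absolute threshold. No morphological
post-processing is applied — the mask is exactly the thresholded set.
Background subtraction by a large-sigma Gaussian rather than a rolling
ball keeps the operation separable (fast in 3D) and monotone for
blob-on-slow-background images. Per-marker thresholds default to Otsu on
the filtered channel and are meant to be overridden by a study's fixed
protocol values.

**Morphometry.** Per islet: volume = voxel count × voxel volume; stained
volume fraction = stained voxels inside the islet / islet voxels × 100;
laminin nodes = 26-connected stain components of at least
`min_node_volume` (default the volume of a 3 µm-radius sphere — above
single-voxel speckle, below any genuine "small scattered node");
E-cadherin holes = 26-connected *unstained* components that do not touch
the islet's boundary shell (voxels within `boundary_margin`, default
3 µm, of the surface) and exceed `min_hole_volume`; hole fraction is
their summed volume as a percentage of islet volume. Requiring enclosure
is this package's operational definition of a "central hole": an open
surface indentation is not a hole. Mean intensity is computed on the
raw, unfiltered channel, since reported arbitrary-unit means mention no
filtering. Viability on 2D live/dead images is green area over the area
of the union of green and red, each channel thresholded (Otsu by
default); an image with no stained area yields a distinct
"no stained area" outcome rather than a number.

**Statistics.** Samples are screened with Shapiro–Wilk; when the pooled
within-group residuals fail at `alpha` and all values are positive, a
natural-log transform is applied to the working values — never a silent
shift, and reported means ± SD always describe untransformed data.
Two-by-two comparisons use Welch's t-test by default ("independent
means" does not license equal variances); a pooled-variance mode is
exposed and satisfies the exact F = t² duality with the one-way ANOVA on
two groups. Pearson's correlation handles the structural associations
(node count vs islet volume, hole volume vs islet volume). No
multiple-testing correction is applied by default, matching the
two-by-two reporting convention; a Holm option exists and its use is
recorded in the report.

## The phantom generator

The generator builds islets as volume-normalised random ellipsoids
(perturbation amplitude as a fraction of the radius) on a canvas of
128³ voxels at 1.5 µm isotropic by default, and rasterises structures as
geometric primitives at stated intensities:

* nuclei — non-overlapping 3 µm spheres strictly inside the islet,
  excluded from the scar core (the "scarce nuclei" phenotype);
* laminin — spherical nodes; normoxic profiles plant 5–9 small
  (4–6 µm) scattered nodes, the hypoxic profile 1–2 large central
  condensations whose radius scales as count^(−1/3) (comparable total
  condensed volume for one or two scars);
* E-cadherin — the islet body minus a central spherical cavity, the
  planted "hole";
* CA9 — a rim of configurable thickness around the scar, plus sporadic
  small blobs under normoxia;
* collagen 4 — tubes along random chords (vessel-like tracks);
* fibronectin — the boundary network of a seeded Voronoi partition of
  the islet interior (intercellular mesh), condensing into the scar.

Rendering follows the standard fluorescence camera model: anisotropic
Gaussian PSF blur (σ_xy = 1.5 µm, σ_z = 3 µm — the axial-resolution
penalty of light-sheet detection), then signal-dependent Poisson noise
(scale 2 AU/photon) plus additive Gaussian read noise (SD 120 AU),
clipped to the 16-bit range. Identical spec + seed gives bit-identical
output; per-structure RNG substreams are derived at fixed offsets so
adding one structure never reshuffles the others.

Ground truth records the pre-blur, pre-noise masks, planted node count
and centres, the planted hole fraction (exactly the voxel ratio), and
per-structure intensities. Two generator invariants are load-bearing for
testing: with blur and noise disabled, thresholding any channel at half
its planted intensity recovers the planted mask voxel-for-voxel; and in
"well-separated" mode node centres keep a pairwise distance of at least
2 × (node radius + σ(d)), where σ(d) is the PSF width *along the
displacement direction*. The direction-dependent form is deliberate: for
a pair of nodes displaced mainly axially, the valley between them is
governed by σ_z, and a bound using only σ_xy admits configurations whose
blurred images merge at any workable threshold.

**Intensity scales.** No intensity statistics are available for the real
acquisitions, so phantom levels are free parameters with documented
defaults (structure levels 3000–6000 AU, in-islet baseline 300 AU,
outside 50 AU), not estimates of real data. The one exception is
E-cadherin, whose per-condition mean levels are set to the reported
group means (8598 / 6463 / 14805 AU for ND1 / ND5 / HD5) so that the
intensity phenotype is exercised on a realistic scale.

**Condition profiles.** `condition_profile()` encodes the three groups:
node counts drawn from {5..9} (normoxia) versus {1, 2} (hypoxia); hole
fractions from truncated normals centred on the reported group values
(2.5 / 3.1 / 8.6%); CA9 as sporadic blobs (normoxia) versus a 6 µm rim
around the scar (hypoxia). Islet radii are drawn U[30, 48] µm from a
substream keyed only by cohort seed and islet index, so cohorts of
different conditions at the same seed are exactly size-matched — this is
the built-in null for the islet-volume ANOVA.

**Viability images.** Non-overlapping islet silhouettes whose pixels are
partitioned into green and red angular sectors such that the planted
green/(green+red) ratio hits the target within one pixel; rendering
reuses the blur+noise model in 2D.

## Study configuration and problem sizes

The phantom study configuration (`phantom_study_config()`) fixes: no
extra per-channel smoothing (the rendered PSF already band-limits the
signal); laminin threshold 1800 AU — the half-maximum of the
*PSF-attenuated* amplitude, since the smallest nodes are comparable to
σ_z and their peaks reach only ~0.8 of nominal, and thresholding at the
unattenuated half-maximum (2150 AU) erodes them below `min_node_volume`;
CA9 threshold 2650 AU (half-maximum, the rim is thick enough not to need
the attenuation correction); Otsu for the islet surface and the
E-cadherin channel, whose brightness varies by condition.

Problem sizes are chosen for single-CPU desk-scale runs: recovery
studies use the cohort default of 64³ voxels at 2 µm (20 phantoms per
condition), the replicated power/level study uses 56³ at 2 µm
(50 replicate cohorts of 8 islets × 3 conditions), and the analytic
sphere checks use 160³ at 1 µm. The vignette's narrative is validated by
the test suite and `scripts/acceptance.R`, which recompute all numbers.

## What passing tests do and do not show

The phantoms exercise threshold placement under blur and
Poisson–Gaussian noise, anisotropic geometry, enclosure topology,
seeded reproducibility and the statistical workflow end to end. They do
not emulate light-sheet stripe artifacts, refractive-index mismatch,
depth-dependent attenuation, antibody penetration gradients, chromatic
registration error, or real vascular topology; tissue autofluorescence
appears only as a flat in-islet baseline. Recovery on phantoms therefore
validates the *computational* pipeline, not the staining protocol;
thresholds for real acquisitions remain a per-protocol calibration that
the config file records.

Known quantitative limits, measured by the acceptance suite: hole
fractions are recovered within ±15% relative only when the cavity is
well above the voxel and `min_hole_volume` scales — normoxic-scale holes
(fractions below ~1%, cavity radii of 2–3 voxels) are at the
quantization floor and may be reported as 0; detected cavity volume is
biased slightly low because axial blur fills the cavity boundary from
both sides. Node counting is exact only under the well-separated
constraint; real condensed laminin need not respect it, in which case
counts are a lower bound (merged components), partially compensated by
reporting node volumes alongside counts. Profiles draw node counts
independently of islet radius, so the positive correlation between node
count and islet volume seen in real islets is not planted: the Pearson
route is exercised on phantom cohorts, but its coefficient there is
expected to sit near zero.

## Numerical choices

Gaussian blur is separable with per-axis banded kernel matrices,
truncated at 4σ, rows renormalised at the array edges (replicate-style
boundary, preserves flat fields). The distance transform is the exact
squared-Euclidean lower-envelope algorithm with anisotropic spacing;
voxels beyond the array faces count as background. Connectivity is 26
for foreground, 6 for background floods (the complementary pair that
keeps enclosure well-defined). Stain binarisation is strict (`> t`), so
a threshold equal to the channel maximum yields an empty mask and
raising the threshold can only remove voxels. Watershed floods from
markers in decreasing distance order with a priority queue; ties fall to
scan order, which is fixed, so repeated runs are identical. Intensities
are never rescaled on I/O; 8-bit input is promoted to the working range
without scaling.
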