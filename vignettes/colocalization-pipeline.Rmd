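---
title: "Quantifying enzyme colocalization in hyphal confocal volumes"
author: "hyphacoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enzyme colocalization in hyphal confocal volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyphacoloc)
```

## The problem

Filamentous fungi compartmentalize parts of their secondary metabolism in
the endoplasmic reticulum (ER) and in sub-micron ER-derived vesicles. Given
a two-channel confocal z-stack — a red reference protein marking those
compartments and a green candidate enzyme — the degree of colocalization is
quantified by correlating the two channels' voxel intensities over the
region where both signals are present. This package implements that
pipeline (segmentation, masked coefficients, 4D object analysis, group
statistics) and, because suitable raw microscopy data are rarely shareable,
a synthetic-scene generator with known ground truth against which every
stage is validated.

## Segmentation model

The two channels are segmented differently, reflecting their different
background structure:

* **Green**: a single two-class Otsu threshold. Candidate thresholds are
  histogram bin centers; the one maximizing the between-class variance
  wins, ties going to the smallest candidate so results are reproducible
  across platforms. Foreground is `intensity > threshold`.
* **Red**: the diffuse cytosolic background is brighter and noisier, so a
  two-class cut cannot separate background, diffuse signal and bright
  compartments. A three-class multi-Otsu (exhaustive search over all
  ascending pairs of bin centers, lexicographically smallest tie) provides
  two cuts; only the brightest class is kept. The binary mask is then
  cleaned by a 3D morphological opening with a 6-connected cross of radius
  1 voxel — the minimal despeckler, removing single-voxel noise while
  leaving compact structures intact. Opening is anti-extensive, idempotent
  and monotone, and the test suite verifies all three laws on fuzzed masks.

Two numerical choices deserve a note. First, histograms use 256 bins;
integer-valued data whose range fits the budget get unit-width bins centred
on the integer intensities, so thresholds are exact intensity values and
the `>` rule classifies boundary intensities the way the class partition
intends. Floating-point data use equal-width bins over the observed range.
Second, the order of the red-channel steps is threshold → binarize → open:
opening is defined on a binary image, so it cannot precede the threshold
that creates one. Whether the original workflow opened per 2D slice or in
3D is not determinable from its description; we open in 3D, consistent
with analysing 3D stacks as volumes.

## Colocalization coefficients

The analysis region defaults to the **intersection** of the two foreground
masks — the most literal reading of "overlapping pixels" — with union and
whole-volume modes selectable. Over that region we report:

* Pearson's correlation coefficient (PCC), the headline statistic;
  undefined (NaN, qc-flagged) if a channel is constant over the region.
  An empty region is a qc-flagged result too, so batch runs over dozens of
  images never abort.
* Manders M1/M2 and the mask Jaccard overlap, as the co-occurrence
  complements to the correlation-based PCC. The original description names
  only "several coefficients including the Pearson's correlation"; M1/M2
  and Jaccard are the field-standard choices for the unnamed ones.

PCC is computed over the whole 3D region, not per slice. For 4D series the
per-timepoint coefficients are summarized by the sign of the least-squares
slope of PCC against time.

## The synthetic scene generator

`scene_spec()` describes geometry in micrometres, discretized onto an
anisotropic voxel grid (default 0.25 × 0.1 × 0.1 µm — a typical confocal
z-step ratio). A scene contains a cytosolic cylinder (radius 1.6 µm), an
axial ER tube (0.5 µm), one perinuclear ring (nuclear envelope, continuous
with the ER — it intersects the tube so the two form one connected
component, as in real hyphae), and `n_vesicles` spheres of radius
0.2–0.35 µm placed by seeded rejection sampling in the annulus between tube
and cell wall. Each vesicle is dual-labelled with probability `f`
(`coloc_fraction`), otherwise a fair coin assigns it to one channel; the
realized fraction is recorded as ground truth. A minimum clearance of
0.3 µm between distinct structures guarantees — given the default voxel
size — that no two ground-truth objects can touch even diagonally after
discretization, so component counts are exactly checkable.

`acquisition_spec()` is the forward optics/detector model, applied in this
order: green→red bleed-through (`alpha`, one-directional by default because
the artifact of interest is a bright green fluorophore leaking into the red
detector; a symmetric option exists), separable Gaussian PSF blur
(σz = 0.2 µm, σxy = 0.08 µm), per-channel photobleaching `exp(-k t)`,
Poisson shot noise at `photon_gain` expected photons per unit intensity
(default 25 — a dim, noise-limited acquisition), and additive Gaussian read
noise (sd 3 photons), clamped non-negative. `photon_gain = Inf` with zero
read noise and zero blur is the exact noiseless identity used by the
truth-recovery tests.

### Why these defaults

The free parameters (structure intensities, densities, optics) are not
stated by any source; they were fixed once, at design time, so that the
generator reproduces the qualitative regimes the pipeline must
discriminate, and they are deliberately not tuned per experiment:

* **Vesicle brightness 2.0 vs ER 0.65.** Sub-micron vesicles lose most of
  their peak intensity to the PSF; at equal nominal brightness a blurred
  vesicle is indistinguishable from the ER plateau and the masked PCC
  stops responding to `f`. A threefold nominal contrast keeps blurred
  vesicles above the ER level, which is also what real confocal images of
  bright puncta look like.
* **ER tube radius 0.5 µm with σz = 0.2 µm.** A thinner tube is all blur
  gradient and no plateau; since both channels share the ER geometry,
  gradient voxels inside the analysis region are perfectly correlated
  between channels and would report strong PCC even for fully segregated
  vesicles. A post-blur plateau plus the noise-limited gain (25
  photons/unit) keeps the fully segregated scene near zero PCC while fully
  colocalized low-noise scenes approach PCC ≈ 1.
* **Read noise as a fixed floor.** PCC is invariant under affine rescaling
  of either channel, so photobleaching alone cannot change it; it is the
  unbleached noise floor that drags the correlation down as the red signal
  decays — the live-cell decay regime.

### What the generator does not emulate

Hyphal branching and septation, nuclear crowding, realistic optical
aberrations (only a Gaussian PSF), detector offset/gain maps, and focus
drift. Passing tests on these scenes therefore demonstrate correctness of
the algorithms and the qualitative regimes, not instrument-level realism;
absolute PCC values from real microscopes depend on optics and expression
levels and are not comparable number-for-number.

## Object analysis

Connected components are labelled under 6/18/26-connectivity (default 26 —
vesicles are compact blobs) via a voxel adjacency graph; labels are
deterministic (ordered by first voxel in array order) and verified against
a flood-fill oracle. Centroids are physical (voxel `i` centred at
`(i − 0.5)·d` µm). Per-object overlap fractions against the other
channel's mask expose the micro-segregation regime: adjacent red-only and
green-only vesicles with sub-micron centroid distances but zero voxel
overlap — same compartment neighbourhood, low image-level PCC.

Tracking is greedy nearest-centroid matching between consecutive frames,
bounded by `max_step_um`, with deterministic tie-breaks (smaller label id).
Scenes have few, well-separated objects, so a global assignment would add
complexity without changing results; determinism matters more here.
`advance_time()` clips moving vesicles to the volume but does not forbid
them from drifting against the ER complex, so segmentation-derived object
tables can show merge events — the tracking accuracy property is therefore
tested on ground-truth-derived tables, which is the linker's actual
contract.

## Group statistics

Strain-level summaries are mean ± SEM (n−1 denominator). Cross-strain
comparison is one-way ANOVA followed by Dunnett's many-to-one test against
the control. The Dunnett adjustment is computed by seeded Monte Carlo:
under H0, group means are `N(0, 1/n_g)` and the pooled variance is
`χ²_df/df`; the max-|t| statistic over all comparisons (correlated through
the shared control) is simulated `n_draws` times and the adjusted p-value
is the exceedance probability, floored at the unadjusted p-value. This
avoids external quadrature tables, is reproducible given a seed, and at
the default 10⁵ draws is accurate to ~0.002 — ample for significance
tiers. The test suite checks the single-comparison limit against the
pooled t-test, cross-checks a three-group case against the multivariate-t
implementation in `multcomp`, and verifies empirical family-wise error
calibration at α = 0.05 under the null.

## Problem sizes

Validation uses 16 × 96 × 96 voxel scenes (4 × 9.6 × 9.6 µm) with 12
vesicles, 20 seeded replicates per colocalization level, 10-frame
time-lapse series, and 2000 simulated null experiments at 10⁴ Monte-Carlo
draws each for the calibration check — sizes chosen so the full validation
runs comfortably on a laptop while keeping Monte-Carlo error well below
the effect sizes being tested.

## Known limitations

* Only TIFF volumes are read and written; proprietary vendor formats are
  out of scope, and TIFF storage is unsigned-integer based (16-bit exact
  for integer data, fixed-point at ~1.5·10⁻⁵ resolution otherwise).
* Multi-Otsu supports three classes (the pipeline's use case), not
  arbitrary class counts.
* No deconvolution: the generator emulates post-processing-grade images
  directly.
* Tracking has no split/merge handling; it is not a general-purpose
  particle tracker.
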