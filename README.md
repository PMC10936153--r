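# hyphacoloc

Quantitative colocalization analysis of two-channel 3D/4D confocal volumes
of fungal hyphae.

When two enzymes of a biosynthetic pathway are tagged with spectrally
distinct fluorophores (say, a DsRed-tagged reference protein marking the
endoplasmic reticulum and its derived vesicles, and a GFP-tagged candidate
enzyme), the question "are they in the same compartment?" becomes a
statistical one: do the red and green voxel intensities co-vary where the
two signals overlap? `hyphacoloc` implements an automated pipeline for that
question, together with a ground-truthed synthetic-scene generator used to
validate every stage.

## The method

For each 3D image (or each timepoint of a 4D live-cell series):

1. **Channel-specific segmentation.** The green channel is thresholded with
   a single two-class Otsu cut (the threshold maximizing the between-class
   intensity variance of the histogram). The red channel has a noisier,
   diffuse background, so a three-class multi-Otsu is used instead: the two
   cuts `t1 < t2` maximize the between-class variance over all ascending
   pairs of histogram bin centers, the brightest class (`I > t2`) is kept,
   and the binary mask is cleaned by a 3D morphological opening
   (erosion-then-dilation with a 6-connected cross).
2. **Colocalization coefficients** over the overlap of the two masks:
   - Pearson's correlation coefficient
     `PCC = Σ(R−R̄)(G−Ḡ) / sqrt(Σ(R−R̄)² Σ(G−Ḡ)²)` over the region voxels,
   - Manders split coefficients `M1`, `M2` (co-occurring fraction of each
     channel's integrated intensity), and the mask Jaccard overlap.
3. **Object analysis**: 3D connected-component labeling (26-connectivity by
   default), per-object channel overlap fractions, green-over-red masking,
   and greedy nearest-centroid tracking across timepoints.
4. **Group statistics**: per-strain mean ± SEM, one-way ANOVA, and a
   Dunnett many-to-one comparison whose family-wise null distribution of
   max |t| is simulated by seeded Monte Carlo.

The synthetic generator builds hyphal scenes (cytosolic cylinder, axial ER
tube, perinuclear rings, sub-micron vesicles) in physical micrometres on an
anisotropic voxel grid, with a controllable fraction `f` of dual-labelled
vesicles, then images them through a forward model: green→red bleed-through,
Gaussian PSF blur, per-channel photobleaching, Poisson shot noise and a
Gaussian read-noise floor.

## Worked example

```r
library(hyphacoloc)

spec  <- scene_spec(coloc_fraction = 0.75, seed = 42)
scene <- make_scene(spec)
scene
#> <ground_truth_scene> 16x96x96 voxels, 12 vesicle(s), realized coloc fraction 0.5

pair <- render_scene(scene, acquisition_spec(seed = 42))
coloc_image(pair, image_id = "demo")
#> <coloc_result> demo: pcc = 0.5156, m1 = 0.816, m2 = 0.173, overlap = 0.088 (1550 voxels, intersection)
```

With 12 vesicles and `f = 0.75` the realized dual-labelled fraction for
this seed is 0.5 (Bernoulli draws), and the masked PCC of 0.52 sits exactly
in the partial-colocalization regime; `m1 = 0.82` says most red intensity
lies inside the green mask.

Comparing a fully segregated "cytosolic control" against a fully
co-compartmentalized strain, eight simulated images each:

```r
pcc_for <- function(f, seeds) sapply(seeds, function(s)
  coloc_image(render_scene(make_scene(scene_spec(coloc_fraction = f, seed = s)),
                           acquisition_spec(seed = s + 1)))$pcc)
dat <- data.frame(value = c(pcc_for(0, 1:8), pcc_for(1, 9:16)),
                  group = rep(c("sphC_control", "sphA"), each = 8))
aggregate_groups(dat, "sphC_control", n_draws = 1e5, seed = 1)$summary
#>          group n    mean    sem qc_small_n    p_adj stars
#> 1         sphA 8  0.6441 0.0165      FALSE 8.58e-12   ***
#> 2 sphC_control 8 -0.0761 0.0313      FALSE       NA  <NA>
```

The compartmentalized strain shows a strongly positive mean PCC, the
segregated control is indistinguishable from zero, and the Dunnett-adjusted
comparison is highly significant.

A command-line interface (`exec/hyphacoloc`) exposes the same pipeline as
`simulate`, `analyze`, `timeseries`, `objects` and `aggregate` subcommands
operating on multi-page TIFF volumes and CSV tables.

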