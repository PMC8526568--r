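# gtpcoupling

Tools for asking, quantitatively, whether RAC1 activity in motile tumor
cells tracks the local availability of free GTP — and whether the enzyme
that supplies that GTP (IMPDH2) plausibly touches RAC1 at a physical
interface. The package is written for cell biologists and image analysts
working with ratiometric biosensor time-lapse data, and for computational
biologists running coevolution-based interface predictions.

It has two independent arms plus synthetic-data generators that make every
stage verifiable without any experimental data:

1. **Imaging arm.** Cells co-express a FRET-based RAC1 activity sensor
   (donor / FRET / acceptor channels) and a GEVAL ratiometric sensor of
   free GTP (Ex409 / Ex494 channels; GEVAL30 is half-maximal at
   K_eff = 32.3 µM, its GTP-blind "null" variant is the negative control).
   Raw five-channel stacks pass through the full correction chain — dark
   current, per-wavelength shading, bead-based affine registration,
   per-frame background subtraction, Otsu segmentation, background-range
   pixel exclusion — before computing two per-pixel indices:

   * GTP index = Ex409 / Ex494,
   * FRET index R = (FRET − α·Donor − β·Acceptor) / Donor, with
     bleed-through fractions α, β estimated from single-fluorophore
     control cells,

   each photobleach-corrected by a fitted double exponential. The readout
   is one pixel-wise Pearson r per frame, summarized per cell
   (mean/median/quartiles) and compared between groups by Mann–Whitney;
   paired cell-body vs protrusion (CB/CP) GEVAL ratios are compared by
   two-tailed t-tests.

2. **Coevolution arm.** Ortholog alignments of two proteins are
   concatenated by species; inter-protein evolutionary couplings are
   estimated by mean-field DCA (sequence reweighting at 80% identity,
   pseudocount regularization, Frobenius-norm scores with average-product
   correction; a pseudolikelihood option exists), smoothed by a 2-D
   Gaussian convolution, and thresholded at the top 5%. Significance comes
   from a species-shuffle randomization test: one protein's sequences are
   reassigned to species N times and p = exceedances / N (3 of 100
   replicates ⇒ p = 0.03).

The methods vignette (`vignettes/dual-biosensor-coupling.Rmd`) documents
the models, defaults, and design decisions in detail.

## Worked example

Simulate one ground-truthed dual-biosensor cell (latent GTP/activity
correlation ρ = 0.49), run the complete correction + index + correlation
pipeline, then run the coevolution pipeline on a simulated pair of
alignments with a planted five-pair interface:

```r
library(gtpcoupling)

cfg   <- scene_config(rho = 0.49, seed = 7)
scene <- simulate_scene(cfg, sensor_model(keff = 32.3))
ana   <- analyze_scene(scene$stack, scene$bundle)
ana$record
#> cell correlation: 30 frames, mean r = 0.470, median = 0.473 [Q1 0.464, Q3 0.477]
sprintf("alpha = %.4f, beta = %.4f", ana$alpha, ana$beta)
#> "alpha = 0.1998, beta = 0.0999"

run <- run_coevolution_pipeline(
  sim = list(len_a = 30, len_b = 30, n_species = 200, n_planted = 5),
  n_replicates = 25, seed = 1)
head(run$top_pairs, 5)
#>    i  j     score
#> 1  7 11 10.181121
#> 2 25 29  9.305042
#> 3  1 14  8.004535
#> 4  2 18  7.805158
#> 5  4 23  7.672942
run$outcome
#> randomization test (max): 0/25 exceedances, p = 0 [(k+1)/(N+1) = 0.0384615]
```

The per-cell mean r of 0.470 recovers the planted ρ = 0.49 to within the
sensor-nonlinearity and shot-noise attenuation (a few hundredths); the
estimated bleed-through matches the generator's true α = 0.2, β = 0.1 to
four decimals; and the five top-ranked coupling pairs are exactly the five
planted interface pairs (`run$truth$pairs`), with no shuffle replicate
reaching the original signal's threshold.

## Analysis workflow

The `analysis/` scripts are thin numbered drivers over the package and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_imaging.R` | renders one ground-truthed scene; stack to `scratch/`, latent-truth table to `results/` |
| `02_imaging_correlation.R` | GEVAL30 vs null-sensor cells through the full pipeline; per-cell r table + Mann–Whitney |
| `03_cbcp_quantification.R` | paired CB/CP GEVAL ratios, enriched and null scenarios, paired t-tests |
| `04_coevolution_interface.R` | planted-interface alignments; couplings CSV + 100-replicate randomization report |

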