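---
title: "Methods: dual-biosensor GTP/RAC1 correlation and coevolutionary interface prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-biosensor GTP/RAC1 correlation and coevolutionary interface prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gtpcoupling` implements two quantitative procedures around the biology of
GTP-driven RAC1 signalling in cell protrusions: (i) a ratiometric
dual-biosensor imaging pipeline that measures the pixel-wise spatiotemporal
correlation between RAC1 activity and free intracellular GTP, and (ii) a
direct-coupling analysis (DCA) of two proteins' ortholog alignments that
predicts an interaction interface and attaches a randomization p-value to
it. Both arms ship with forward-model generators that produce ground-truthed
synthetic inputs, so every stage of the computation can be verified without
any external data.

# The imaging arm

## Sensors and indices

Free GTP is read out by a GEVAL-class ratiometric sensor. Its response is
modelled as a single-site saturating hyperbola

$$ r(c) \;=\; r_\min + (r_\max - r_\min)\,\frac{c}{K_\mathrm{eff} + c}, $$

with $K_\mathrm{eff} = 32.3\ \mu M$ for GEVAL30 (the concentration at 50% of
the maximal ratiometric signal; the sensor responds from roughly
$4\ \mu M$ and approaches saturation near $100\ \mu M$). A Hill coefficient
is configurable but defaults to 1, since only $K_\mathrm{eff}$ and the
saturation range are characterized. $r_\min$ and $r_\max$ are not
characterized either; the defaults (1 and 3) are arbitrary and configurable
— every downstream statistic is invariant to them because the Pearson
correlation is computed per frame and is unchanged by affine rescaling of an
index. The GTP-insensitive "null" variant returns $r_\min$ at any
concentration and serves as the negative control throughout.

The two per-pixel indices are:

* **GTP index** — the ratio of GEVAL fluorescence excited at 409 nm to that
  excited at 494 nm.
* **FRET index** — the bleed-through-corrected ratio
  $R = (\mathrm{FRET} - \alpha\,\mathrm{Donor} - \beta\,\mathrm{Acceptor}) /
  \mathrm{Donor}$, where $\alpha$ and $\beta$ are the fractions of donor and
  directly excited acceptor emission contaminating the FRET channel,
  estimated as zero-intercept regression slopes on cells expressing a single
  fluorophore. This printed ratio formula is used as the single per-pixel
  activity index (with $\alpha = \beta = 0$ when no control stacks are
  supplied).

## Correction chain

Corrections run in a fixed order that the pipeline runner enforces:

1. **Dark current**: per-channel dark frames subtracted; negatives are
   clipped to 0. Clipping is a package choice made for ratio stability — on
   noise-free input it changes nothing, and on real input it only touches
   pixels that the background-range rule later excludes anyway.
2. **Shading**: division by unit-mean per-wavelength reference images (from
   a uniform dye solution). A stack can be shading-corrected only once.
3. **Registration**: the GEVAL camera is mapped onto the reference camera by
   one least-squares affine estimated from fiducial beads and applied to all
   frames (no per-frame drift model); resampling is bilinear and
   out-of-bounds pixels become invalid.
4. **Background**: per frame and channel, the mean of a cell-free region is
   subtracted; the region's standard deviation defines the *background
   range*.

Segmentation takes the donor channel (best signal-to-noise at the cell
edge), applies a per-frame Otsu threshold whose series is smoothed by an
edge-truncated temporal median (window 5, toggleable — a stand-in for
MovThresh-style smoothing), and keeps the largest connected component.

Pixels are retained for statistics only if, **in every channel**, the
intensity exceeds the background level by $k$ background standard deviations
($k = 2$ by default; the "background range" itself is not a published
definition, so mean + $k\cdot$s.d. is the package's operationalization, with
$k$ exposed in the options). Per-channel background levels are used; whether
levels should be pooled across channels is not documented anywhere we know
of, and per-channel is the conservative choice.

## Photobleach correction

The whole-cell mean index per frame is fitted to
$m(t) = a_1 e^{-k_1 t} + a_2 e^{-k_2 t}$ (non-negative amplitudes and
rates) and each frame is divided by $m(t)/m(0)$. Fitting uses
Levenberg–Marquardt least squares with multi-start initialization ($k_1,
k_2$ log-spaced over $[10^{-4}, 1]$ per minute, $a_1 = a_2 = m(0)/2$),
keeping the lowest-SSE fit; failures fall back to a single exponential and
then to an uncorrected stack with a warning flag. A constant series
short-circuits to the identity. At least 6 frames are required (4 free
parameters). The correction is applied to both the FRET and the GTP ratio
by default (configurable) — note that because it multiplies each frame by a
positive scalar, it cannot change any per-frame Pearson correlation; it
matters for index interpretability and CB/CP quantification, not for the
correlation statistics.

Because the photobleach stage is a *fit* rather than a stored correction
asset, the package's exact forward/inverse consistency check (corrected
indices equal the latent maps to $<10^{-6}$ relative error on noise-free,
bleach-free scenes) is run with this stage disabled: dividing by a fitted
near-constant curve perturbs frames at the $10^{-4}$ level.

## Correlation statistics

One Pearson $r$ is computed per image over the jointly valid pixels (frames
with fewer than `min_pixels = 100` valid pixels, or zero variance in either
index, are skipped) — frames, not pixels-over-time, are the correlation
unit. Per cell, the retained per-frame $r$ values are summarized by mean,
median and quartiles (the bar-and-whiskers convention: whiskers are the
first and fourth quartiles, the median splits the bar). Groups of cells are
compared on their per-cell mean $r$ by a two-sided Mann–Whitney test: exact
mid-rank enumeration when both groups have $\le 8$ cells, a tie-corrected
normal approximation otherwise. CB/CP ratio tables are compared by a
two-tailed paired t-test (or Welch's unpaired variant; the plain label
"unpaired Student's t-test" is interpreted as Welch since equal variances
are never guaranteed). All p-values are two-sided.

## The synthetic scene generator

The generator is a forward model of everything the correction chain
undoes. Latent fields are smooth Gaussian random fields (spatial scale 3 px)
evolving as temporal AR(1) processes (coefficient 0.8) over 30 frames at
1-min spacing, mimicking live-cell dynamics on a 144×144 grid whose cell
mask (ellipse body + protrusion lobe) holds ≥10⁴ pixels. The in-mask
correlation between the GTP and activity fields equals the target $\rho$
*exactly in every frame*: the activity field is built as
$\rho\,\hat g + \sqrt{1-\rho^2}\,\hat e$ with $\hat e$ explicitly
orthogonalized against $\hat g$ within the mask. Latent GTP fluctuates
around the GEVAL30 $K_\mathrm{eff}$ (mean 32.3, s.d. 8 µM), keeping the
sensor in its responsive range; the nonlinearity of the sensor response and
the shot/read noise attenuate the recovered correlation by a few percent at
high $\rho$, which is the main reason the end-to-end recovery tolerance is
±0.05 rather than ±0.01.

Channels carry a few thousand counts of in-cell signal with Poisson shot
noise (gain 0.5) plus Gaussian read noise (s.d. 2 counts) — a generic sCMOS
model, chosen because the acquisition hardware's noise is not characterized
in a reusable form. Shading uses fixed per-wavelength off-centre vignettes
(channel-specific optical centres, amplitude 0.15 by default), dark current
is a constant offset (100 counts), background fluorescence drifts slowly
(30 ± 3 counts), each fluorophore bleaches by its own double exponential,
and the GEVAL camera is misregistered by a small affine (default translation
(1.0, −0.7) px). Bead coordinates consistent with the true affine, dark
frames, mean-1 shading references, a cell-free background region and
donor-only/acceptor-only control stacks are bundled with every scene.

What the generator does **not** emulate: optical point-spread blur, 3-D
z-structure, cell movement/deformation of the mask over time, spatially
correlated camera noise, and saturation/clipping of the detector. Passing
tests therefore demonstrate the correctness and calibration of the
*computational* chain, not robustness to every physical artifact of real
microscopes.

## Problem sizes

The test-suite scale was chosen to exercise the study conditions while
staying desk-sized: 10 cells × 30 frames for the null-sensor calibration;
10 seeds per $\rho \in \{0, 0.25, 0.5, 0.75\}$ (plus $\rho = 0.49$, the
reported GEVAL30 mean) for recovery; 10 seeds for the correction-necessity
contrast at shading amplitude 0.3 with $\alpha = 0.2$, $\beta = 0.1$.

# The coevolution arm

## Couplings

Two ortholog sets (one aligned sequence per species) are concatenated by
their shared species into a cMSA; only the inter-protein block of coupling
scores is reported. The default estimator is mean-field DCA: sequences are
reweighted at 80% identity, single and pair frequencies are blended with a
relative pseudocount of 0.5 (half the probability mass to the uniform
distribution — the field's customary regularization), gaps are counted as a
21st state, and couplings are read off the negative inverse of the
correlation matrix over the 20 amino-acid states. Pair scores are Frobenius
norms of the 20×20 coupling blocks in zero-sum gauge (gap state excluded),
followed by the average-product correction computed on the full score
matrix. Singular correlation matrices trigger one retry with a larger
pseudocount.

A pseudolikelihood option is provided as per-site ridge-penalized
multinomial logistic regression (L2 penalty 0.01, asymmetric estimates
averaged), which is a pseudolikelihood-maximization estimator implemented on
a robust convex solver rather than a bespoke conjugate-gradient optimizer;
it is considerably slower and intended for small alignments or spot checks.
Mean-field is the default everywhere for desk-scale speed.

## Convolution, threshold and the randomization test

The inter-protein score block is smoothed with a normalized 2-D Gaussian
kernel (σ = 2 columns by default — the source convolution's width is not
restated anywhere accessible, so 2 columns is the package's choice,
configurable), reflective at the boundary. The interface threshold is the
minimum score of the top 5% of the convolved signal. Significance comes from
species-shuffle randomization: protein A's sequences are randomly reassigned
to species, the cMSA rebuilt and the convolved couplings recomputed, 100
times by default; `p = exceedances / replicates` exactly (so 3 of 100 gives
0.03), with the `(k+1)/(N+1)` estimate reported alongside for reference.

The published description of what counts as an exceedance is ambiguous —
"number of predicted contacts higher than a predefined threshold" in one
sentence, replicates whose "minimum score" beats the threshold in the next —
so three statistics are implemented and selectable: the default (a replicate
exceeds when the **maximum** of its convolved block beats the threshold,
the most conservative reading), a count statistic (at least as many
above-threshold pairs as the original's top set), and a top-minimum
statistic. None is asserted to be the historically exact choice.

**Contact identification vs interface significance.** Individual contact
predictions (`top_coupling_pairs`, precision-at-k) rank the *unconvolved*
APC-corrected scores. Smoothing deliberately trades per-pair localization
for spatial clustering: around a strong peak, kernel neighbours outrank
weaker genuine pairs, so convolved scores are the right input for the
threshold-and-randomize interface test but the wrong one for naming residue
pairs. This split is a package design decision.

**Phylogenetic confounding.** The species shuffle destroys shared phylogeny
as well as direct coevolution, so two proteins that merely evolved on the
same species tree can yield a small p-value without any planted coupling.
The calibration suite therefore builds its signal-free null from ortholog
sets generated on *independent* trees; the shared-tree case is documented
here as a known, inherent limitation of randomization tests of this design.

## The alignment simulator

Sequences evolve down a shared random coalescent tree (`ape::rcoal`,
rescaled to unit root-to-tip depth) with independent per-column
substitution; the default of 6 expected substitutions per column
corresponds to deep divergence, giving columns substantial diversity (a
prerequisite for covariation signal — near-conserved columns carry almost
none, which is equally true of real alignments). Planted inter-protein
pairs co-substitute: the protein-B member mirrors the protein-A member
through a pair-specific random residue bijection with probability equal to
the coupling strength, per species. Species labels are assigned to tips at
random because coalescent tip numbering correlates with topology — left
unshuffled, the label index itself would leak relatedness between
independently generated alignments. Benchmark scale: 500 species, 60+60
columns, 5 planted pairs at strength 0.9, 10 seeds.

# Numerical choices and degenerate inputs

* Ratio denominators below $10^{-6}$ × frame maximum are invalidated rather
  than divided by.
* Dark-subtraction negatives clip to 0; shading references must be strictly
  positive with mean 1 ± 10⁻⁶.
* Percentiles and quartiles use linear interpolation (R's type-7).
* Constant frames segment to an empty mask with a warning; constant index
  series short-circuit photobleach correction to the identity; zero-variance
  samples give flagged (NA-p) test records instead of errors.
* Exact Mann–Whitney enumeration is used when both groups have ≤ 8
  observations (mid-ranks for ties; two-sided p is twice the smaller tail,
  capped at 1); the normal approximation is tie-corrected and applied
  without continuity correction, which holds the measured type-I error at
  n = 10 within [0.03, 0.07].
* All generators and the randomization test are fully seeded; identical
  configuration and seed give bit-identical output.

# Known limitations

* The imaging generator's defaults encode one moderate-noise acquisition
  regime; the recovery tolerances quoted above are calibrated to it, not to
  arbitrarily noisy data.
* Mean-field DCA degrades on very gappy or very shallow alignments (a
  warning fires below 50 sequences); the pseudolikelihood option does not
  scale to long concatenated alignments in pure R.
* The randomization test inherits the phylogenetic confounding discussed
  above; a significant p-value supports shared evolutionary signal at the
  interface, not physical contact by itself.
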