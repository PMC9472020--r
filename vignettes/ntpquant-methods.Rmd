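---
title: "Methods: models, parameters and validation of ntpquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation of ntpquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ntpquant` packages the quantitative analyses of a preclinical non-thermal
plasma (NTP) melanoma therapy study: per-cell immunofluorescence
quantification anchored on DAPI, dual-marker double-positive counting,
discharge pulse-energy dosimetry, and preranked gene-set enrichment driven
by a combined significance score. This vignette explains each model, the
parameters that matter, what the synthetic generators emulate (and what
they deliberately do not), and the numerical choices behind the
implementation.

## 1. Nuclei segmentation and per-cell quantification

### The operator chain

`segment_nuclei()` applies, in order:

1. **One-sided low-pass background removal** (`subtract_background()`,
   `background_sigma` = 40 px). The background estimate is a Gaussian blur
   of the image itself; it is subtracted and negative residuals are clipped
   at zero. A wide kernel passes nuclei (tens of pixels) almost untouched
   while absorbing illumination gradients. We read "one-sided" as this
   subtract-and-clip: it removes background while keeping intensities
   nonnegative, the only interpretation consistent with both goals.
2. **Percentile saturation and normalization** (`saturate_normalize()`,
   `saturation_percentile` = 95). Values above the 95th percentile of all
   pixels of the channel are capped at it, then the image is min–max
   rescaled to [0, 1] — the "normalized dynamic range". A constant image
   maps to all zeros rather than NaN (degenerate-input safety).
3. **Binarization** (`binarize()`, `binarize_fraction` = 0.40). Pixels at
   or above 0.40 of the normalized range are foreground; the `>=`
   convention makes boundary behavior deterministic.
4. **Connected components and size filter** (`label_nuclei()`,
   `min_object_px` = 20, 8-connectivity). 8-connectivity is the standard
   blob-detection convention; it is configurable. No large-object filter is
   applied to DAPI — in the source protocol that filter is specific to the
   marker-object analysis.
5. **Analysis regions** (`build_analysis_region()`,
   `analysis_dilation_px` = 5). Each nucleus is dilated by the Euclidean
   distance transform; pixels claimed by several nuclei go to the nucleus
   with the nearest centroid, exact ties to the lower cell id — a
   deterministic, input-order-independent rule. The dilation radius is not
   fixed by the source protocol; 5 px is our default and it is exposed as a
   parameter rather than guessed.

The chain is gain-invariant: multiplying the raw image by any positive
constant leaves the binary mask unchanged, because the percentile cap and
the min–max rescale absorb the gain. This matters for batch-processed
slides imaged at shared but arbitrary capture settings.

### When the 0.40 threshold is meaningful: percentile anchoring

The fixed-fraction threshold presumes the 95th percentile lands on *signal*.
If nuclei (plus any other bright structure) cover less than 5% of pixels,
the cap lands inside the noise distribution instead. Two structural
consequences follow, independent of the noise level:

* at zero noise the percentile of a sparse field is 0 and the saturation
  step blanks the image;
* with homoscedastic pixel noise of any standard deviation, the threshold
  `0.40 * q95` sits at about 0.7 noise standard deviations, so a fixed
  ~20% of background pixels binarize to foreground and percolate into
  8-connected clusters larger than the 20 px filter (we measured tens to
  hundreds of spurious objects per 512 x 512 field in that regime).

The method is therefore a *dense-field* method — appropriate for tumor
sections, where nuclei occupy well over 5% of a field. The synthetic scenes
used for validation respect this: the high-power geometry places 10–100
nuclei of radius 20–23 px (a ~13 µm melanoma nucleus at 40x-equivalent
sampling) on a jittered grid in a 512 x 512 field, giving 5.3%–66% nuclear
coverage at every count. Sparse-and-small scenes are outside the method's
domain, by design, and `saturate_normalize()` is not the place to fix that.

### Per-cell quantification and fold change

`quantify_cells()` averages a *background-subtracted but unnormalized*
marker channel over each cell's analysis region, keeping per-cell means on
the linear intensity scale; the slide-level statistic is the unweighted
mean of per-cell means (each cell counts equally, matching the per-cell
reading of the protocol rather than a pixel-pooled mean).
`fold_change()` reports the ratio of group means of slide means and the
per-slide ratios to the control mean, so dispersion can be judged either
way (per-slide normalization before or after averaging).

Two multiplicative attenuations affect absolute per-cell means: the
Gaussian high-pass removes the fraction of blob signal present in its own
local blur, and the region mean dilutes a perinuclear blob by the
blob-to-region area ratio. Both are shared between treatment groups, so
*ratios* — the quantities interpreted in such studies — are unaffected; the
acceptance run recovers a planted 1.33x shift to within ±0.01 on average.
Absolute calibrated intensities are not a goal.

## 2. Double-positive counting

`marker_objects()` takes a marker channel preprocessed by the same
subtract/saturate/normalize chain, binarizes it at the channel threshold
(defaults 0.3 for GFP/CD3, 0.2 for TxRed/FOXP3), removes masked pixels that
overlap neither nuclei nor cytoplasm, labels 8-connected components and
keeps objects of 20–500 px. "Cytoplasm" is operationalized as the analysis
ring (dilated nucleus minus nucleus); the source protocol names cytoplasm
without defining it, and the ring is the deterministic surrogate consistent
with the nucleus-anchored design. Masking *precedes* labelling, so an
object's size is its size within cell regions.

`call_positivity()` marks a cell positive for a channel when at least one
surviving object overlaps its region by at least `min_overlap_px` pixels
(default 1 — the protocol says "overlapping" without a fraction; the
parameter exists for stricter settings), and double positive when both
channels hit. By construction the double-positive count can never exceed
either single-positive count, and counts are invariant to cell label order
and channel processing order.

The two-marker validation scenes use a denser, smaller-nucleus geometry
(~150 cells of radius 6–9 px per 512 x 512 field, 10x-like sampling) so
that marker blobs (nucleus + 2 px) fall inside the 20–500 px window while
nuclear coverage stays ~10%. At zero noise, calls match planted labels
exactly; at pixel noise of 10% of signal, pooled precision and recall stay
above 0.95 because the surviving noise exceedances are isolated pixels
removed by the small-object filter.

## 3. Pulse-energy dosimetry

Instantaneous power is `P(t) = V(t) I(t)`; per-pulse energy is the Riemann
sum `sum_k V_k I_k * dt` over the recorded window (`dt` = 50 ns,
`n` = 2000 by default). Negative partial powers are physical (capacitive
back-flow) and are retained. The displacement-current contribution —
recorded with the applicator far from the target, where no discharge
forms — is subtracted *as an energy*, `eps = eps(discharge) −
eps(displacement)`, exactly as the dosimetry model states; pointwise
waveform subtraction would give a different number and is deliberately not
used. No probe-delay deskew is applied (none is applied in the reference
setup).

The synthetic generator uses damped-sinusoid templates
(`V0 e^{-t/tau} sin(wt)` against a current lagging by `phase_lag`) whose
overlap energy has a closed form, plus square pulses for exact
`V * I * width` checks. The displacement current is a second damped
sinusoid scaled so that it carries a stated fraction of the discharge
energy; because energy is linear in current at fixed voltage, the analytic
energies add exactly. Defaults (18 kV, 0.28 A, 500 kHz, tau = 2 µs) give a
2 µs-wide ~0.9 mJ pulse — the microsecond-DBD regime of the in vivo
system. On this grid the left Riemann sum is within 0.33% of the analytic
integral (the leading error term vanishes because the integrand is ~0 at
both window ends), and halving `dt` shrinks the error at first order or
better. Total dose is `eps * frequency * time`; the worked example
0.9 mJ x 700 Hz x 10 s = 6.3 J is exact. `distance_sweep()` aggregates
replicate corrected energies per application distance as mean ± SEM
(SEM undefined and flagged for a single replicate).

## 4. Significance-score ranking and preranked enrichment

Each gene's ranking score is `pi = log2FC * (-log10 p)` — odd in the fold
change, strictly increasing in magnitude as p shrinks. Upstream p-values of
0 (reported by some DE tools) are clamped to the smallest positive double
with a warning rather than dropped, preserving the gene; this is
configurable. `rank_genes()` sorts by decreasing `pi` with lexicographic
tie-breaks, so the ranking is a pure function of the table.

The source protocol names preranked GSEA but not its internals, so we
implement the community-standard statistic and declare the choices:

* **Running sum**: walking down the ranking, add `|pi|^p / N_R` at set
  members (`p` = `weight_exponent`, default 1) and subtract `1/(N - N_hit)`
  at non-members; ES is the signed maximum deviation, and the leading edge
  contains members at or before (after, for negative ES) the extremum. A
  set covering the whole ranking, or none of it, has no contrast and is
  flagged degenerate with ES = 0. Under equal weights the ES of a set and
  of its complement are exact negatives.
* **Null**: `n_perm` (default 1000) random gene sets of matching size drawn
  from the ranked universe — the gene-label permutation null, shared across
  sets of equal size.
* **NES**: ES divided by the mean |null ES| of matching sign.
* **FDR q**: the standard preranked ratio of null and observed tail
  fractions at the set's NES, per sign, capped at 1.
* **Size window**: sets with fewer than 5 or more than 500 members in the
  ranking are excluded and recorded.

The implementation is cross-checked in the test suite against an
independent brute-force running sum on small instances and against
`fgsea::calcGseaStat` on random instances; `fgsea` is never used as the
implementation.

The synthetic DE generator plants sets as disjoint blocks of the gene
universe: null genes draw `log2FC ~ N(0, 0.5)` and `p ~ U(0, 1)`, planted
genes draw `log2FC ~ N(effect, 0.5)` and `p ~ Beta(0.25, 1)` (the standard
null/alternative emulation for enrichment recovery; it makes no claim about
count-level RNA-seq noise). A planted 30-gene set at effect size 1.5 is
detected at FDR <= 0.05 in 20/20 seeds at 1000 permutations.

## 5. Study-level summaries and the pipeline runner

`tumor_volume()` implements the caliper formula `0.5 * length * width^2`
and enforces `length >= width > 0`, because swapping unequal diameters
changes the volume. `group_summary()` reports mean ± SEM (sd/sqrt(n), NA
and flagged for n = 1) and the treated/control ratio of means (undefined
and flagged when the control mean is 0). Mixed-model and survival inference
are intentionally out of scope — those are off-the-shelf statistics; the
package emits tidy per-slide tables for any statistics environment.

`run_pipeline()` chains the stages from a YAML or list config, seeds every
stage from one top-level seed, and writes a JSON report whose provenance
block carries the package version, seed and the complete parameter set;
rerunning the same config reproduces the payload byte for byte (no
timestamps are embedded). The package's functions and this runner are the
interface; there is no shell CLI.

## 6. What the generators emulate — and what passing tests do not show

The image generator renders uniform-intensity disks with per-cell
brightness jitter on a smooth background with additive Gaussian pixel
noise, clipped at zero. The default background is a low-order polynomial
ramp: a degree-<=2 polynomial passes through a sigma = 40 px Gaussian blur
essentially unchanged and is removed almost exactly by the high-pass. A
wide Gaussian *bump* background is also available, but note that a bump of
sd ~150 px is **not** fully removed (about 7% of its amplitude survives the
high-pass as one huge smooth residual), which after normalization can
surface as a giant spurious object — a genuine failure mode of the chain
worth knowing about with real vignetting.

Not emulated: optics/PSF blur, signal-dependent (shot) noise, textured
tissue autofluorescence, touching or overlapping nuclei (no watershed
splitting exists in the chain, so none is planted), z-stacks, and spectral
bleed-through. Passing the recovery suite therefore shows the operator
chain is implemented correctly and behaves as designed on dense,
well-separated fields; it does not certify performance on crowded or
out-of-focus real tissue.

The waveform generator produces ideal damped sinusoids; real scope traces
add quantization, trigger jitter and probe deskew, none of which are
modeled (an optional sample-shift parameter exists but defaults to 0). The
DE generator emulates a DE *summary table*, not reads or counts — upstream
alignment and differential testing are out of scope.

## 7. Problem sizes used in validation

The test suite and the acceptance script use: 50 noisy 512 x 512
segmentation fields with 10–100 nuclei each; 3 + 5 two-marker 150-cell
fields; 5 slides per group x 20 seeds for the fold-change study; 6
displacement fractions (0–0.5) for dosimetry; and 20 seeds x 1000
permutations for enrichment power. These sizes give stable pooled
statistics (thousands of cells, tens of independent fields) while the whole
suite runs in about a minute on a single core.
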