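---
title: "Methods: semi-supervised residual-tumor assessment from slide patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-supervised residual-tumor assessment from slide patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdistill)
```

## The estimation problem

After neoadjuvant therapy, pathologists grade treatment response on resection
slides by estimating the *residual viable tumor percentage*: the area of
viable tumor divided by the area of the tumor bed, where the tumor bed is the
union of viable tumor, necrosis and stroma (summing to 100%). Two categorical
endpoints derive from it: **pCR** (pathological complete response, no viable
residual tumor at all) and **MPR** (major pathological response, at most 10%
viable residual tumor). Visual percentage estimation is subjective — junior
pathologists in particular tend to overestimate — which motivates an
automated, reproducible estimator.

`pathdistill` casts the problem as patch classification. A pathologist-drawn
tumor-bed mask is tiled exhaustively into non-overlapping 256×256 patches at
the working magnification (20×; the pipeline trusts the manifest and never
resamples). Each patch is classified *viable tumor present* vs *absent*, and
the slide percentage is the positive share of the tumor bed. Supervision is
deliberately cheap: a small set of patch-level binary labels plus the routine
slide-level percentage estimates, which are *noisy* — clinically meaningful
but imprecise.

## Model

Patches are embedded by a **frozen encoder** and classified by a trainable
**two-layer head** (D → H → 2, ReLU, softmax). The built-in encoder is a
hand-crafted 36-dimensional descriptor — per RGB channel an 8-bin intensity
histogram, mean, standard deviation, and the mean and standard deviation of
per-pixel gradient energy — chosen so that desk-scale experiments need no GPU
or pretrained weights; `encoder_spec()` is the adapter point for any external
deep feature extractor. Because the encoder is frozen and deterministic,
identical patches always yield identical features, which makes the whole
training loop reproducible from one seed.

The head is trained by mini-batch Adam on class-weighted cross-entropy.
Inverse-frequency class weights matter here: on near-pCR slides positive
patches are rare, and an unweighted loss collapses to the majority class.

## Two-step training with percentage-guided pseudo-labels

1. **Step 1 — supervised.** Train the head on the human patch labels alone.
2. **Step 2 — distillation.** For every training slide, score all unlabeled
   tumor-bed patches and rank them by predicted tumor probability
   (descending; ties broken by ascending grid position so the ranking is
   total and reproducible). With `N` unlabeled patches and pathologist
   percentage `p`, let `k = round(p · N)` (half away from zero — stated
   explicitly because the rounding rule is observable in tests). Ranks
   `1..k` with probability ≥ `theta_pos` (default 0.8) become pseudo-positive;
   ranks beyond `k` with probability ≤ `theta_neg` (default 0.2) become
   pseudo-negative. Both gates must agree: the percentage caps *how many*
   positives a slide may contribute, the confidence gate vetoes *which*.
3. Retrain the head **from scratch** (fresh seeded initialization) on human ∪
   pseudo labels, and iterate (default 3 rounds). Retraining from scratch
   rather than fine-tuning prevents early pseudo-label mistakes from
   compounding across iterations, and is simpler to make exactly
   deterministic.

Design choices in this loop that were genuinely open, and how we resolved
them:

- **The exact pseudo-label rule** (cutoff + symmetric confidence gates,
  pseudo-negatives included) is our reconstruction; all three knobs are
  exposed in `distill_config()`. Conservative defaults (0.8 / 0.2) keep
  label noise from flooding the training set.
- **Re-ranking pool.** Each iteration re-ranks the *full* unlabeled pool
  rather than only never-labeled patches: pseudo-labels are provisional by
  construction, so letting a later, better model revoke them is the safer
  convention.
- **Iteration count.** "Several iterations" is fixed at 3 by default;
  the per-iteration log (`tidy()` on the fit) shows pseudo-label counts
  stabilising after 1–2 rounds on synthetic cohorts.
- **Degenerate iterations.** If an iteration produces no pseudo-labels at
  all (e.g. every slide is pCR and the negative gate is unreachable), the
  iteration falls back to step-1 training with a warning. A single-class
  pseudo batch is *not* degenerate — human labels always contribute both
  classes.
- Human labels are immutable, and the pseudo-positive count per slide never
  exceeds `k`; both are asserted in code.

## Slide assessment

`estimate_fraction()` offers two denominators because "positive patches
divided by tumor bed area" can be read two ways: `count` mode (default) uses
the patch count; `area` mode weights each patch by its tissue fraction. They
differ only at bed borders and coincide exactly when tissue fractions are
equal. Patch positivity uses threshold 0.5 on the calibrated softmax.

pCR is called iff the predicted fraction is exactly zero — no positive patch
anywhere — matching the endpoint's definition literally; a `pcr_epsilon`
band exists in configuration for continuous estimators but is off by
default. MPR is `fraction ≤ 0.10` with an inclusive boundary. The robust
accuracy band is likewise inclusive (`|y − ŷ| ≤ τ`); with the exact
definition unavailable we chose `≤` and state it.

Interpretability outputs mirror routine sign-out: per-slide likelihood
heatmaps on a fixed cool-to-hot colormap (with an exact numeric matrix file
alongside every image), galleries of the k most and least tumor-like
patches, and per-channel RGB bin counts inside the tumor bed as a
cross-scanner color QC.

## Agreement metrics

`r2_score()` is the coefficient of determination against the stated
reference (the senior consensus), not a symmetric correlation; it can be
negative. `mae_mse()` and `robust_accuracy()` complete the suite. RAcc is
read as tolerance-band accuracy on the fraction scale (RAcc at 0.1 = within
10 percentage points) — the only reading under which less experienced raters
can sit near 0.5 at the tight band yet above 0.9 at the loose one.
`observer_report()` scores any number of prediction sources (model, junior
raters, …) against one reference, including pCR/MPR call concordance, with
`autoplot()` scatter panels.

## The synthetic cohort generator

No real slides ship with the package, so the generator is first-class,
tested code that defines the study conditions for every end-to-end claim.
Per slide it draws a grid of 256×256 patches (10–20 rows and columns by
default, i.e. roughly 100–400 patches — whole-slide tumor beds scaled to
desk size), a pCR indicator (probability 0.25, matching the reported 32/128
cohort rate), and a non-pCR viable fraction from Beta(1.2, 3), whose mass
near small fractions reproduces a realistic MPR share. Tumor patches are the
top-`k` cells of a Gaussian-smoothed random field (smoothing σ = 2 patch
units), so the realized tumor count equals `round(fraction · N)` exactly and
tumor forms contiguous nests as in real regression beds; with σ = 0 the
placement is provably exchangeable. A second field places necrosis (30% of
non-tumor patches); necrosis belongs to the tumor bed but never to viable
tumor. The pathologist label is the true fraction plus clipped Gaussian noise
(SD 0.05 on the fraction scale), and per-cohort additive RGB shifts emulate
scanner differences.

Textures are statistical stand-ins, not histology: tumor = dark nuclei-like
ellipses (high gradient energy, with per-patch density jitter so some tumor
patches are genuinely hard), stroma = smooth oriented fiber stripes,
necrosis = low-saturation mottle. Sparse patch annotation is emulated by
labeling 120 random training patches (a fraction of a percent of the patch
population, proportionally similar to real annotation budgets). What the
generator does **not** model: stain physics and H&E variability, rater-
specific bias structure (noise is symmetric Gaussian, real juniors
overestimate), magnification errors, or pen/fold/blur artifacts. Passing
tests therefore demonstrate the *pipeline logic* — ranking, gating,
aggregation, metrics, reproducibility — not clinical-grade accuracy on real
scans.

## Numerical and reproducibility choices

- All pixel coordinates are 0-based with half-open extents; the patch grid
  is anchored at the tumor-bed bounding-box origin, and grid identity is
  row-major. Patch admission needs tissue fraction ≥ 0.5 by default.
- Polygons rasterize with the even-odd rule by pixel-center test — both
  choices made for deterministic, oracle-checkable behavior.
- Every stage seed derives from one global seed via a stage-name hash
  (`stage_seed()`), training shuffles and initialisations included, so two
  runs with the same config and seed produce byte-identical summary JSON.
- Ranking ties, top/bottom-patch ties, and `k`-rounding all have stated,
  tested tie-breaks.

## Problem sizes

The validation cohort used throughout tests and the acceptance script is 50
slides (40 train / 10 test) with 10–20 patch grids (~10,000 patches), head
width 16, 60 epochs, 3 distillation iterations — sizes chosen so a complete
run finishes in minutes on one CPU while leaving the classification task
non-trivial (sparse labels, jittered textures, noisy percentages). Smaller
cohorts (4–20 slides, 2–9 grids) are used for unit-level properties.

## Known limitations

- The built-in encoder is a deliberate desk-scale descriptor; real
  deployments should plug a pretrained histology encoder into
  `encoder_spec()`.
- Tumor beds are always inputs — the package does not segment them.
- Slides are flat rasters (PNG); pyramidal WSI formats are out of scope.
- The label-noise model is symmetric; systematic rater bias is only
  represented in evaluation fixtures, not in the generator's label model.
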