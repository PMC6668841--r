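---
title: "Visual timelines: model, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual timelines: model, generator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the representation

Most of the predictive content of an inpatient electronic health record is
longitudinal but not image-shaped: vitals charted roughly hourly, labs every
few hours, medication orders, interventions, nurse examinations. `vistl`
renders the first 48 hours of one admission as a **visual timeline** — a
V x 48 grayscale matrix with clinical variables on the vertical axis, hours
since admission on the horizontal axis, and pixel intensity equal to the
normalized value. A convolutional network with a recurrent layer (CNN-RL)
then predicts in-hospital mortality occurring after hour 48, and Grad-CAM
maps its attention back onto the picture so a clinician can see *where* in
the record the risk signal lives.

The encoding pipeline is:

1. **Hourly blocking.** Bins are 0-based and half-open, `[h, h+1)`. The
   latest observation inside a bin wins; exact-timestamp ties resolve to the
   later input row. Both rules are arbitrary but fixed, which makes the
   encoding a pure function of the observation set.
2. **Carry-forward (LOCF).** Each empty bin inherits the most recent earlier
   value of its variable.
3. **Location-median imputation.** Bins still empty (before the first
   observation, or for never-observed variables) receive the training-split
   median of that variable at the admission's location, falling back to the
   global training median and finally to the plausible-range midpoint.
   Binary variables impute 0 (absence). All statistics are fitted on the
   training split only and carry their provenance; encoding asserts it, and
   model training refuses any batch containing a validation admission.
4. **Static rows.** Age, sex, race, comorbidity count, and an admission
   location one-hot are rendered as constant rows across all 48 columns.
5. **Normalization.** Two schemes. *min-max*: bounds per variable, black =
   low, white = high. We use the training 1st/99th percentiles (clipped to
   the plausible range) rather than raw extremes, so a single aberrant value
   cannot compress the whole dynamic range of a channel; raw extremes remain
   available via `raw_minmax = TRUE`. *custom*: direction-aware, black =
   clinically normal, white = abnormal. Higher-abnormal variables scale as
   min-max; lower-abnormal variables are inverted (low urine output maps
   towards white); variables abnormal in both directions map the magnitude
   of the departure from the training mean, scaled per side so that either
   bound of the plausible range reaches 1. A "mean zero, one = away from
   the mean" rule admits a signed and a magnitude reading; we chose the
   magnitude mapping because a single gray scale cannot carry sign without
   a second channel, and flag it as a sensitivity-analysis knob.
6. **Row ordering.** *standard* keeps variables grouped by type.
   *within-group* and *across-group* cluster variable rows by Pearson
   correlation pooled over training cells (distance `1 - r`, complete
   linkage) and use the dendrogram leaf order, inside each group block or
   globally. Zero-variance rows get correlation 0.

# The synthetic cohort generator

The study cohort this package emulates is single-center EHR data that was
never deposited, so everything here is testable only against a synthetic
stand-in. The generator is deliberately the *simplest* process that yields
learnable spatio-temporal structure, not a physiological simulation.

One latent scalar severity per admission drives everything. Per admission:

* location ~ categorical (ward .309, ED .414, ICU .055, other .222 —
  the marginal mix of the published cohort);
* a patient-level severity set point: location baseline plus N(0, 0.32)
  frailty; ICU baselines are highest, procedural/"other" lowest;
* a per-admission deterioration slope N(0, 0.012)/hour — the time-ordered
  component of risk;
* an hourly mean-reverting walk around the drifting set point
  (reversion 0.12, innovation s.d. 0.10), started at stationarity;
* mortality from a logit in the 48-hour maximum severity, the late-minus-
  early severity trend, age, and sex;
* length of stay from an outcome-conditional lognormal floored at 2 days
  (the design includes only admissions of at least 48 hours, and deaths
  occur after hour 48 by construction).

Observations are emitted per variable as a Poisson process (vitals ~hourly
with a guaranteed reading in the first hour; labs ~6-hourly; nurse
examinations ~4-hourly; orders sparser, with rates that increase with
severity — sick patients generate more "activity"). Continuous values are
`normal + sign(direction) * link * severity + noise`, clipped to the
plausible range; binary values are Bernoulli with a severity-linked logit;
consciousness is banded (AVPU levels and GCS 15/13/10/6) from thresholds on
noisy severity.

**Calibration.** The defaults were tuned once, by coordinate iteration on
simulated cohorts of 400k-800k admissions, to reproduce the published
cohort marginals: 2.5% mortality; ICU admission 25% among deaths vs 5%
among survivors; mean age 63 vs 55; 47% vs 57% female; median stay 9 vs 5
days. The emission links were likewise calibrated so the comparators behave
as reported: vital signs move little per severity unit relative to their
measurement noise (so MEWS bands fire late — the published MEWS
discrimination is modest), the SOFA organ inputs are weak late markers, and
the remaining channels (lactate, white count, bicarbonate, hemoglobin,
urine output, Morse/Braden scores, medication and intervention activity)
carry the bulk of the severity signal. That distribution of signal is what
makes a whole-picture model out-discriminate a five-vital track-and-trigger
score, which is the qualitative finding the package reproduces.

**What the generator does not model** — and hence what passing tests do not
show about real data: no real disease physiology or organ-system structure;
no correlations between variables beyond the one shared latent factor (and
the per-admission sign flip for bidirectional variables); no transfers
between units (imputation uses the admitting location for all 48 h, and the
location-stratified evaluation stratifies by admission location rather than
location at 48 h); no informative missingness beyond the severity-scaled
observation rates; no measurement artifacts. A model that wins here wins a
much cleaner game than a hospital provides.

# Models

No deep-learning framework ships with this package's environment
assumptions, so the three architectures, backpropagation, Adam, and the
Grad-CAM hook are implemented directly in RcppArmadillo (all heavy lifting
is BLAS). All gradients are verified against central finite differences in
the development history; the Grad-CAM path is verified in the test suite
against a hand-rolled oracle on a single-filter toy network.

* **standard_cnn** — the MNIST-style stack: two 3x3 conv blocks (ReLU,
  2x2 max-pool), a dense ReLU layer, sigmoid output.
* **rnn** — a GRU over the 48 hourly column vectors, sigmoid on the last
  hidden state.
* **cnn_rl** — two 3x3 conv blocks whose pooling collapses only the
  variable axis (2x1), so all 48 time steps survive; each time step's
  feature column feeds a GRU; sigmoid on the last hidden state. Grad-CAM
  targets the second conv block's activations — the final convolutional
  layer — with gradients flowing back through the recurrent head.

Defaults: 8 and 16 filters, recurrent width 32, dense width 32, dropout
0.3 on the penultimate features, Adam at 1e-3, batch 128, at most 16
epochs with early stopping (patience 5) on tuning-split AUC, inverse-
prevalence class weights, decoupled weight decay 1e-4, and Gaussian input
noise (s.d. 0.05) as augmentation. The sizes are deliberately small: the
documented experiment (five seeds, 8,000 admissions, two architectures)
runs in minutes on one CPU, and on these synthetic images larger nets were
checked and do not discriminate better — with ~110 positive training
admissions the binding constraint is regularization, not capacity, which
is also why the weight decay and noise augmentation exist: without them
the class-weighted fit memorizes the positives.

The split protocol is the study's: 70% derivation / 30% held-out
validation, then 80/20 inside derivation for training vs tuning, all at
admission level, seeded.

# Evaluation and interpretation

Discrimination is AUC (mid-rank Mann-Whitney) with DeLong 95% intervals
and paired DeLong tests between models on the same admissions (the
standard test for correlated AUCs; a score-swap permutation oracle
cross-checks it in the tests), plus step-wise average precision, whose
no-skill baseline equals the 2.5% prevalence. The single-pixel
perturbation probe zeroes one uniformly random pixel per validation image
and recomputes AUC — on the default experiment the change is below 0.005,
the null effect the robustness narrative expects.

Grad-CAM: channel weights are spatial means of the death-logit gradient at
the final conv layer, the map is the ReLU of the weighted activation sum,
bilinearly upsampled (the canonical choice) and scaled to max 1. Because
the channel weights are spatial *means*, the map's row profile is carried
by the activations, and activations track pixel intensity; a meaningful
localization check therefore needs an image in which only contributory
cells are bright. The packaged localization experiment is designed
accordingly: a dynamic-channels-only catalogue (no constant demographic or
location rows), the custom normalization (clinically normal = black), all
demographic coefficients zero, equal location baselines, and severity
links confined to the contiguous laboratory block — so the designated
rows are the only systematically bright, outcome-linked region, and mean
attention over them exceeds the complement across seeds. On the full
default cohort, where nearly every channel carries signal and constant
demographic rows are mid-gray, per-row attention contrasts are not
informative, and the differential image is the better cohort-level
localization tool. The
differential image subtracts the mean timeline of deaths from that of
survivors; white marks the most discriminative cells. Overlay PNGs blend
the grayscale base towards a blue-to-red palette with weight equal to the
attention, so full attention renders pure red; row labels ship in a JSON
sidecar rather than being rasterised into pixels, keeping the PNG bytes a
deterministic function of the matrices.

# Numerical and degenerate-input choices

* Constant training channels: normalization bounds fall back to the
  plausible range, with a warning.
* Zero-variance rows in ordering: correlation 0 to every other row.
* Pooling windows: ReLU'(0) = 0 and argmax ties take the first (topmost)
  cell; both are measure-zero choices that only matter for exactly-equal
  values.
* An all-zero Grad-CAM map stays zero rather than being rescaled.
* Identical score vectors in the paired test return p = 1 (the DeLong
  variance degenerates).
* AVPU and GCS are ordinal but ride the continuous machinery with banded
  emission; their MEWS/SOFA bands are half-open intervals like every other
  component, and the banding tables are CSV fixtures, not code, so variant
  site bandings can be swapped in.
* SOFA's cardiovascular component receives a dose-less vasopressor flag, so
  the dose-graded rows collapse to 3 (vasopressor) and 4 (vasopressor with
  hypotension); the renal urine-output band is off by default because an
  hourly grid carries a rate, not a 24-h total (enable `include_urine` to
  use a trailing-rate approximation from hour 24).

# Problem sizes used by the shipped checks

The packaged checks run a 50,000-admission cohort for generator
calibration, 1,000 random sparse records against a scalar blocking/LOCF
reference, 10,000 random panels against the score oracles, n = 200
bootstrap/permutation comparisons for the AUC machinery, and five seeded
8,000-admission end-to-end experiments for the discrimination-ordering,
perturbation, and Grad-CAM-localization checks. These sizes are the
package's documented desk scale: large enough that the Monte-Carlo error
of each quantity is small against its tolerance, small enough to run
routinely.

# Known limitations

* The generator's single latent factor means inter-variable correlation
  structure is unrealistically simple; ordering schemes therefore have less
  to work with than on real data.
* The full 156-variable preset pads the named clinical variables with
  generic numbered lab/medication channels to preserve the matrix shape;
  the padded channels are thin stand-ins, not clinical content.
* Probabilities are not calibrated (no Platt/isotonic step); only ranking
  metrics are reported.
* The deep pretrained-CNN family is out of scope; the comparison triple
  standard CNN / RNN / CNN-RL preserves the ablation logic without
  pretrained weights.
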