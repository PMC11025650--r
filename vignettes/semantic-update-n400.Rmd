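---
title: "Semantic update, surprisal and the N400: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic update, surprisal and the N400: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model the package implements, the
choices that were genuinely open when building it, and what its synthetic
test bed does and does not establish.

## The two accounts of the N400

The N400 is a centro-parietal negativity peaking around 400 ms after word
onset, graded by cloze probability, congruity, priming, frequency and
sentence position. Two mechanistic accounts are contrasted here:

1. **Semantic prediction error.** Comprehension maintains an implicit,
   predictive representation of the sentence's meaning. Each word updates
   it; the N400 tracks the size of the update.
2. **Lexical prediction error.** Comprehension predicts the next word; the
   N400 tracks surprisal, `-ln P(w_t | context)`.

Both are implemented as recurrent networks over the same input and
recurrent stack so that the *training task* — meaning prediction versus
next-word prediction — is the only substantive difference between them.

## The Sentence Gestalt model

The update network maps word `t` through a learned embedding into a
one-layer LSTM; the hidden state `sg_t` ("Sentence Gestalt") summarizes the
sentence so far. The query network receives `sg_t` and a probe and must
output the complete role-filler vector of one event argument through a
logistic output layer.

A role-filler vector is the concatenation of three blocks: `F` binary
filler features, an `R`-way role one-hot, and a `K`-way frame one-hot
(`K` = maximal frame index, default 8). A role-probe zeroes the role block;
a filler-probe zeroes the filler block; the frame block stays intact in
both so multi-event sentences remain unambiguous. During training, *every*
probe of the sentence is presented after *every* word, so the network is
forced to anticipate arguments whose words have not yet arrived — this is
what makes the gestalt predictive. Only arguments actually present in a
sentence are probed.

**Semantic Update.** `SU_t = mean(|sg_t - sg_(t-1)|)` with `sg_0 = 0`. Two
readings of "SG layer activation" were possible for an LSTM: hidden state
only, or hidden plus cell state. The hidden (output) vector is what
downstream layers read, so it is the default; `sg_forward(...,
state = "hidden+cell")` exposes the alternative. The sentence-initial SU
equals the mean absolute activation of the first state; it is retained in
the series, with a `drop_first` flag for analyses that discard
sentence-initial tokens.

**Loss accounting.** The aggregation — mean over the probes of a word, sum
over the words of a sentence, mean over the sentences of a mini-batch — is
fixed and recorded in the configuration, because it affects gradient scale
and is otherwise easy to leave implicit. Probe order is frame-major with
the role-probe before the filler-probe; no effect is claimed, it is fixed
for reproducibility.

**Filler representations.** Fillers are binary feature vectors obtained by
thresholding real-valued embeddings at 0 (strictly greater; presence/absence
semantics — the rounding direction is otherwise arbitrary, and the threshold
is exposed). When no embeddings are supplied, `synthetic_features()`
generates independent random binary codes: they carry no distributional
semantics, which is sufficient for the package's synthetic experiments and
is stated wherever they are used. A lexical variant
(`filler_mode = "lexical"`) replaces features by a one-hot over the lexicon,
so the model predicts the word form of the filler instead of its features.
Out-of-vocabulary fillers map to the all-zero feature vector with a warning
rather than erroring, which keeps naturalistic corpora usable.

## The language model

Identical embedding/LSTM/hidden stack, softmax over the lexicon,
cross-entropy on next-word prediction, trained on raw token sequences with
the frame annotation ignored. Surprisal is reported in natural-log units;
the regression is scale-invariant up to the coefficient, so the base only
relabels the axis. A sentence-start symbol conditions the first word, so
first-word surprisal is defined; conditioning is per-sentence, matching
word-by-word sentence presentation. Scoring floors probabilities at 1e-12
(with a warning) so surprisal stays finite. The update of the LM's
recurrent layer (`internal_update()`) uses exactly the SU formula — shared
code — enabling the same analysis on a lexically-trained model's internal
dynamics.

## Training regime

Both models train with Adamax (learning rate 0.01 for the SG model, 0.002
for the LM), mini-batches of 32 sentences, and only sentences with 6-15
tokens and at most 8 frames. 90% of the batches train, 10% validate; the
weights with the best validation loss are kept (early stopping, patience
10, cap 150 epochs at paper scale). The neural nets — LSTM, backprop
through time, Adamax — are implemented in the package itself in vectorized
base R, with sentences of identical shape processed as one batch; gradients
are verified against central finite differences in the test suite
(relative error below 1e-4 at perturbation 1e-5).

The `"desk"` preset (embedding 32, gestalt 64, cap 60 epochs) is the
package's working scale: micro-world corpora of a few hundred sentences
train in seconds and reach the regime where the conditional structure of
the world is learned, which is what the qualitative effect battery needs.
The `"paper"` preset (600/1,200, 150 epochs, 300k lexicon) preserves the
full-scale configuration but requires corpus and compute resources outside
the package's scope.

## The micro-world

`micro_world()` defines a small event world with three templates:
transitive (`the AGENT ACTION the PATIENT .`), located (adds `in the
LOCATION`), and conjunction (`the AGENT sees the N1 and the N2 .`).
Manipulations are pure configuration:

* **Cloze / congruity.** Each action has a patient distribution
  (0.7 / 0.2 / 0.1). The distributions form cyclic triples — each patient
  word is the 0.7-completion of one action, the 0.2 of another, the 0.1 of
  a third — so all patient words have identical marginal frequency and the
  cloze contrast is purely conditional. An incongruent completion is a
  patient from outside the action's support (probability zero in training).
  Without the cyclic design, low-cloze words would also be globally rare,
  and their under-trained embeddings would depress SU for the wrong reason;
  matching marginals removes that confound.
* **Priming.** In the conjunction template the second noun is the first
  noun's partner with probability 0.8, so partners are predictable from
  their primes purely through co-occurrence statistics.
* **Frequency.** Agent sampling weights range from 0.30 to 0.03.
* **Position.** Located sentences are 9 tokens long; SU is examined across
  positions.

`contrast_stimuli()` derives fixed evaluation sentences for each contrast
from the world specification, and `sg_effect_battery()` trains one model
per seed (400 sentences per corpus by default) and measures each contrast's
SU difference; directions are tested with an exact sign test across seeds.
Passing this battery shows that the implementation reproduces the
qualitative effect pattern *within this controlled world*; it does not show
that the desk-scale model generalizes to naturalistic text, which requires
corpus-scale training.

## Synthetic ERP and EEG generators

`generate_erp_trials()` is the generative twin of the analysis model:
fixed effects for baseline, negated SU and surprisal; crossed random
effects (by-subject intercept and SU slope, by-word intercept); Gaussian
noise. Defaults (baseline -0.4, SU 0.2, surprisal 0.15 in standardized
units; SDs 0.5 / 0.1 / 0.3 / 1) echo the magnitudes typical of single-trial
N400 regressions and are defaults, not targets. SU enters negated so the
downstream sign convention (N400 is a negativity; more update, more
negative) is exercised end to end. All latent draws are recorded so fits
can be checked against the exact generating values.

`generate_timecourse()` plants a parametric effect curve `beta(t)` (default
a triangle, whose true fractional-area latency is known) with per-electrode
gains, subject and word intercepts, a constant baseline effect and white
noise. It emulates only the statistical structure the analyses assume — no
realistic spectra, artifacts or electrode geometry.

## Analysis decisions

* **ML, not REML.** The likelihood-ratio and AIC comparisons alter fixed
  effects, which is invalid under REML; all fits are maximum likelihood.
* **Random slopes.** By-subject slopes are fitted for predictors of
  interest, not the baseline covariate. For nested comparisons the random
  structure must be identical in both models, so `fit_mixed_model()` allows
  a slope for a predictor absent from the fixed part, and a
  `fallback = FALSE` switch disables the convergence fallback ladder
  (drop slopes, then intercepts only) that is otherwise applied and
  recorded.
* **P-values.** Satterthwaite degrees of freedom via lmerTest, with a
  normal approximation on the t ratio as fallback; recorded per fit.
* **Standardization.** Predictors (including the baseline) are z-scored by
  default so coefficient magnitudes are comparable across predictors; raw
  scale is retained as an option and used by the recovery simulations,
  whose planted values are stated in standardized units.
* **FDR families.** One family per analysis: all time points of a
  time-course fit, or all electrode-by-window cells of a topography fit,
  corrected together by Benjamini-Hochberg.
* **Fractional-area latency.** Rectified area (`|beta|`) by default — the
  standard choice, robust to sign flips — with a signed option; the
  analysis window defaults to 0-650 ms and is configurable (effect curves
  are sometimes reported to 700 ms). Cumulative area is trapezoidal with
  linear interpolation to locate the crossing; ties resolve to the smallest
  crossing time; a zero-area curve has no latency and errors.
* **Per-subject latencies** come from per-time-point ordinary least squares
  within subject (no subject-level random terms are identifiable there),
  then a two-sided paired t test; subjects with undefined latency are
  excluded and logged. A constant latency difference across subjects has no
  error variance; the test then reports `t = +/-Inf, p = 0` (or `t = 0,
  p = 1` for identical latencies) rather than failing.

## Numerical and degenerate-input conventions

Logistic outputs are clamped to [1e-12, 1 - 1e-12] inside the loss only;
gradients use the unclamped form, which is exact for Bernoulli
cross-entropy. Lexicon ties at the frequency cutoff break
lexicographically. A constant predictor column is rejected with its name.
Zero-variance generators are legal and produce exact linear-predictor data
(used by the exact-recovery tests). Empty corpora, empty electrode sets,
empty sampling grids and zero-area curves raise immediate errors.

## Problem sizes used by the test suite

Simulation sizes were chosen as the smallest at which each property is
stable: parameter recovery at 12 subjects x 600 words (50 replicates);
LRT calibration at 12 x 300 (200 null, 50 effect replicates — at this size
the chi-squared reference is accurate, while much smaller designs make the
test visibly conservative); the effect battery at 10 seeds x 400 sentences;
LM-vs-bigram calibration at 5,000 training sentences; topography null
calibration at 60 replicates of a 4-electrode x 5-window grid with a
binomial allowance for Monte-Carlo error. The demo at desk scale runs in a
couple of minutes end to end.

## Known limitations

* Desk-scale models trained on a synthetic micro-language support
  qualitative, direction-of-effect conclusions; coefficient magnitudes from
  published corpus-scale studies are not reproducible at this scale.
* Random binary filler features ignore semantic similarity between words;
  graded similarity effects that depend on feature overlap are outside the
  battery.
* The EEG generators produce white noise on a fixed grid; autocorrelated
  noise, artifacts and realistic topographies are not modelled, so FDR
  calibration results apply to independent-noise families only.
* The micro-world's congruity contrast uses zero-probability completions;
  reversal anomalies and other structured violations are not represented.
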