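---
title: "Single-neuron odour coding: models, statistics and design choices"
author: "piriform package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-neuron odour coding: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piriform)
```

# Scope

`piriform` implements the analysis pipeline for single-neuron recordings
acquired while participants smell a panel of 15 odours plus an odourless
control (16 stimuli, 8 presentation cycles each: rating on cycles 1–4,
4-alternative identification on cycles 5–8), optionally followed by a
matched 16-image visual block. The pipeline covers five stages:

1. **Responsiveness** — detecting stimulus-modulated neurons with a
   per-neuron one-way ANOVA on baseline-z-scored response rates, plus
   normalized PSTHs, an odour-versus-control contrast, and single-event
   rank-sum tests.
2. **Decoding** — pseudopopulation identity decoding with a
   maximum-correlation-coefficient template classifier,
   label-permutation nulls, window/neuron-count sweeps, session-level,
   cross-modal and chemical-versus-perceived variants.
3. **Population statistics** — Treves–Rolls population sparseness,
   repetition-suppression slopes, valence contrasts and correlations,
   and the exact count statistics (binomial and two-proportion Z tests).
4. **A synthetic-session generator** with full ground truth, so every
   stage can be exercised, calibrated and recovery-tested without
   patient data.
5. **Orchestration** — `runPipeline()` / `renderReport()`.

The package starts from sorted spike times; spike extraction, artifact
removal, electrode localization, respiration analysis and mixed-effects
confirmation models are out of scope.

# Data model and windows

A session (`OdourSession`) holds a neuron table (unit id, region: PC,
AMY, EC, HIP, PHC), per-neuron sorted spike-time vectors in seconds from
session start, and a trial table. All analysis windows are half-open
`[start, end)` seconds relative to trial onset; a spike exactly on the
end boundary belongs to the next interval, which makes window counts
deterministic. Defaults: odours are analysed in [0, 2) s against a
[−5, 0) s baseline; images in [0, 1) s against [−0.5, 0) s.

Per-trial firing rates are assembled into a `RateMatrix`, a
`SummarizedExperiment` whose single assay holds neurons × trials rates,
with the trial table as `colData`. Two normalizations exist:

* **raw** — spike count / window length (Hz; non-negative);
* **z-scored** — per neuron, $z_t = (r_t - \mu_b)/\sigma_b$ where
  $r_t$ is the response-window rate on trial $t$ and $\mu_b, \sigma_b$
  are the mean and standard deviation of the per-trial baseline-window
  rates across the selected trials.

Two choices here were genuinely open and are worth recording. First,
$\sigma_b$ is the *sample* (n − 1) standard deviation of the per-trial
baseline rates — the estimator is not dictated by the procedure
definition, and the sample form matches common practice; because the
same linear transform is applied to every trial of a neuron, the ANOVA
F and p below are identical under either estimator, so nothing
downstream depends on it. Second, baseline statistics are computed from
*per-trial baseline rates* rather than from pooled baseline bins; the
per-trial form ties the normalization to exactly the trials entering an
analysis and keeps subset analyses (e.g. rating-phase only)
self-contained. Neurons with $\sigma_b = 0$ cannot be z-scored; they
are excluded from z-scored matrices and listed in
`metadata()$excluded`, never silently zeroed.

# Detecting stimulus-modulated neurons

For each neuron, a one-way ANOVA tests the z-scored response rate
against stimulus identity across all trials of the block — 128 trials
and 16 groups for a full odour block, giving the classical F(15, 112)
design. The control stimulus counts as a 16th group (that is what the
degrees of freedom imply); `excludeControl = TRUE` reproduces the
15-group variant. Selection is per neuron at a fixed α = 0.05 with *no*
multiple-testing correction across neurons: this is a deliberate
fidelity choice, and its direct consequence — that ≈ 5% of untuned
neurons are flagged — is itself used as the selection procedure's
chance level and is verified by calibration tests. The ANOVA is applied
to z-scored rates for both modalities (stated explicitly for images;
adopted for odours too, switchable by passing a raw matrix), another
place where the choice is immaterial for inference because z-scoring is
a per-neuron linear transform.

The implementation computes F row-wise from between/within sums of
squares, vectorised over neurons; the test suite proves it equal to
`stats::aov()` on random inputs.

# The decoding machinery

**Classifier.** For each class, the template is the mean training
population vector; a test vector is assigned to the class whose
template has the maximal Pearson correlation with it. Zero-variance
test vectors have undefined correlations and draw a uniformly random
class from the tied set (seeded). Ties at the maximum break by a seeded
uniform choice.

**Pseudopopulations.** Neurons recorded in different sessions are
combined by aligning trials with the same stimulus label: for each
class, each neuron's 8 trials are independently shuffled and
concatenated position-wise into 8 pseudotrials. This follows the
trial-alignment semantics of the standard neural-decoding toolboxes;
the procedure is not restated in full in the analysis description, so
it is documented here as an interpretation. With a single session the
pseudotrials are a within-class permutation of the real trials. When a
paired analysis needs the *same* neurons in two pseudopopulations
(cross-modal, chemical vs perceived), the sampled neuron order is held
fixed across the pair.

**Cross-validation.** 8 splits stratified by class
(leave-one-trial-per-class-out for the 8-presentation design), 10
resample runs, accuracy averaged over folds and runs.

**Significance.** The null is built by permuting class labels within
the assembled pseudopopulation before cross-validation — this destroys
stimulus information while preserving each neuron's marginal rate
distribution. p-values use the add-one percentile rule
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_\text{perm})$,
so the smallest attainable value with 1,000 permutations is 1/1001 and
p is never 0. Null accuracies centre on 1/16 = 6.25% for the 16-class
design; the suite checks both this and the uniformity of permutation
p-values under the null.

**Sweeps and onsets.** Window-length and neuron-count sweeps test each
grid point with a right-sided Wilcoxon signed-rank against chance
across subsample runs, Bonferroni-corrected for the grid size. The
decoding *onset* is defined as the first grid point from which
significance is sustained through the end of the grid; "sustained" is
not defined in the source analyses, and requiring significance at every
later grid point is the strictest monotone reading. The
first-presentation-excluded control is exposed as
`dropFirstCycle = TRUE`, not as a default.

# Population statistics

**Sparseness.** For stimulus $k$,
$A_k = \left(\tfrac1N\sum_i x_i\right)^2 / \tfrac1N\sum_i x_i^2$ and
$SI_k = (1 - A_k)/(1 - 1/N)$, where $x_i$ is neuron $i$'s mean raw
response rate in [0, 2) s. Raw (non-negative) rates are required by the
formula; all recorded neurons of a region enter by default (the neuron
set is not restricted in the source definition), with a
modulated-only variant available by subsetting rows. The control is
excluded, and the regional summary averages $SI_k$ over the 15 odours.
Regions are compared by one-way ANOVA over the 15 per-odour SI values
per region with Tukey HSD pairwise tests.

A regime analysis is worth recording, because it constrains what
synthetic tests can show. Write the population as a fraction $f$ of
responders whose rates are an effective factor $c$ above baseline.
Then $A(f) \propto (1 + (c-1)f)^2 / (1 + (c^2-1)f)$, which *decreases*
in $f$ (so SI increases) until $f \approx 0.26$ for the generator's
default effective gain $c \approx 2.9$. In that low-gain regime, adding
responders makes the population *more* heterogeneous relative to its
log-normal baseline spread, and broad tuning raises rather than lowers
SI. Only when evoked responses dominate baseline heterogeneity (large
gain, or near-silent baselines as in real MTL data) does SI become a
monotone decreasing function of tuning breadth. The test suite
therefore checks the breadth ordering in the response-dominated regime
(tight gain ≈ 10) and does not assert a cross-region SI ordering at
the generator's default gain of 2, where it is not identifiable.

**Repetition suppression.** Per neuron, the mean z-scored rate is
computed for each of the 8 presentation cycles (over the 15 odours,
control excluded — "response strength" is read as the mean z-scored
rate of odour-modulated neurons per cycle, the most direct reading),
and a least-squares line is fitted over the 8 cycle means — the slope
is fitted on cycle means, not per-trial points, following the
eight-values-per-neuron construction. Regional significance is a
two-sided signed-rank of slopes against 0, plus a paired
first-versus-second-cycle test for the first-trial effect.

**Valence.** Per (modulated) neuron, mean z on liked minus disliked
rating-phase trials; regional two-sided signed-rank; and a Spearman
correlation between per-odour population-mean z and *external*
reference valence scores with a seeded two-sided permutation p.
Reference scores are always an input vector — they are published
externally and are never bundled. One practical caution the synthetic
cohorts expose: within one session, all neurons responding to the same
odour share that session's realized ratings, so per-neuron contrasts
are correlated and single-session regional tests are anti-conservative;
the pipeline (and the tests) pool neurons across sessions before the
regional test, as the real analysis does.

**Count statistics.** `exactBinomialTest()` implements right, left and
two-sided exact binomial tests. The two-sided convention is the
"small-p" rule — the sum of the probabilities of all outcomes no more
probable than the observed one — matching the exact-test
implementations used for the published worked examples (tail doubling
would not reproduce them). `twoProportionZTest()` uses the pooled
estimator. Both reproduce the published values to printed precision in
the test suite, e.g. overlap p = 8.9 × 10⁻⁸ for 66 of 1,856 at chance
(321/1856)·(185/1856) ≈ 0.017, and Z = 6.5 for 321 vs 185 of 1,856.

# The synthetic-session generator

`generateSession(synthConfig(), seed)` draws a complete session with
ground truth. Design and defaults:

* **Task structure**: 16 × 8 odour trials in pseudorandom order
  (per-cycle seeded permutations with no immediate repeats), mean
  inter-trial interval 19.4 ± 0.4 s; rating cycles 1–4, identification
  5–8; optional 16 × 8 image block at 1 s exposures. The control can be
  omitted (`includeControl = FALSE`), mirroring the one recording
  without it.
* **Rates**: piecewise-constant inhomogeneous Poisson — baseline →
  response plateau at a region-specific latency → baseline. This is the
  simplest model that drives every analysis stage; it deliberately
  omits smooth response kernels, oscillatory/respiratory locking,
  refractoriness and rate drift.
* **Baselines**: log-normal, median 2 Hz, log-sd 0.5 (plausible
  extracellular yields; shared across regions).
* **Tuning**: per-region tuned fractions default to PC 0.40, AMY 0.20,
  EC 0.14, HIP 0.12, PHC 0.05 (the measured modulated fractions);
  preferred-set size is 1 + Poisson, with PC broad (mean 4 odours) and
  AMY/HIP narrow; response gain is Gamma(shape 2, mean 2). Gains and
  breadths are plausible stand-ins, not measured quantities — the
  recordings report no quantitative gain or latency distributions — and
  are fully config-exposed.
* **Dynamics**: response to a preferred stimulus on cycle $c$ is
  $\text{baseline}\times(1 + g\,v_\text{mod})\times d^{\,c-1}$, with
  multiplicative repetition-suppression decay $d = 0.95$, a
  first-presentation boost (×1.5) for PC, and amygdala-only valence
  gain $v_\text{mod} = 1 + \beta_v v_k$ ($\beta_v = 0.5$). The control
  evokes $\text{baseline}\times(1 + 0.3\,g)$ in odour-tuned neurons.
* **Behaviour**: liked with probability $\text{logistic}(2 v_k)$ — a
  generative link chosen so valence analyses are recoverable, not a
  claim about behaviour; identification correct with probability 0.741,
  otherwise a uniform distractor.
* **Cross-modal structure**: a fraction ρ (default 0.2) of odour-tuned
  neurons are also tuned to the congruent images; a further 5% are
  image-only.

Every stochastic entry point requires a seed, and the same
(config, seed) pair yields a byte-identical session. Because the
generator's spike trains are exactly Poisson and its effects exactly
multiplicative, passing recovery tests demonstrates that the estimators
are unbiased and calibrated *under the model's assumptions*; it does
not certify behaviour under bursting, drift, sorting contamination or
respiratory covariates present in real recordings.

# Numerical conventions

* Half-open windows everywhere; boundary spikes excluded
  deterministically.
* Rank tests delegate to `stats::wilcox.test` (mid-ranks; exact
  enumeration for small untied samples, normal approximation with
  continuity correction otherwise).
* Degenerate inputs fail loudly: zero-baseline-variance neurons are
  excluded and logged, constant vectors are an error for rank
  correlations, a pooled proportion of 0 or 1 is an error for the
  Z-test, all-zero activity vectors skip a stimulus with a warning.
* Permutation p-values use the add-one rule and are never 0.

# Problem sizes

The test suite and the acceptance script run on deliberately small
cohorts chosen as the smallest sizes at which each effect is reliably
identifiable: sessions of 6–45 neurons per region for unit tests,
pooled cohorts of 5–6 sessions for regional inference, 150–1,000
permutations for nulls, and 2,000–4,000 untuned neurons for the
selection-calibration estimate. The full-scale defaults (200-neuron
subsamples, 1,000 subsample runs, 1,000 permutations) remain the
package defaults and are practical for real cohorts.

# Known limitations

* The generator shares one baseline-rate distribution across regions;
  real regional differences in baseline rate and recording yield are
  not emulated, which is one reason absolute sparseness values (and the
  cross-region SI ordering at default gain; see the regime analysis
  above) should not be read as predictions about tissue.
* No respiration, electrode geometry or spike-waveform modelling; no
  session-to-session nonstationarity.
* Session-level decoding and the chemical-versus-perceived analysis
  assume the block designs are complete (8 presentations; at least two
  choices per odour label for eligibility), as in the source design.
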