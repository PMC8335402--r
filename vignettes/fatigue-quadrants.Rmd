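---
title: "Fatigue quadrants from HRV and Stroop performance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fatigue quadrants from HRV and Stroop performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvfatigue)
```

## The measurement model

The package scores psychophysiological fatigue from two short
smartphone-grade measurements taken in one sitting:

1. an RR-interval recording, from which the time-domain heart rate
   variability (HRV) statistics and a Baevsky-type stress index are
   computed, and
2. a 35-stimulus Stroop color-word task, from which the mean reaction
   time (RT) and accuracy are computed.

Two binary cuts turn these into a four-level fatigue state. The Stroop
side is *fast* when the session's mean RT is below 500 ms and *slow* at
or above it. The HRV side is *high* when the observed SDNN exceeds an
age-referenced normative SDNN and *low* otherwise. The cross of the two
gives the quadrants `fast_low`, `fast_high`, `slow_low`, `slow_high`
(canonical order; `fast_low` is category 1). A multinomial logistic
model then relates quadrant membership to physiological and lifestyle
covariates.

## HRV metrics and the stress index

For an RR series $x_1, \dots, x_n$ (ms):

* **AVNN** $= \bar{x}$; **heart rate** $= 60000 / \bar{x}$ (bpm).
* **SDNN** $= \sqrt{\sum_i (x_i - \bar{x})^2 / (n - 1)}$. The sample
  (n−1) denominator is the default because it is the standard unbiased
  choice for short recordings; `sdnn(rr, sample = FALSE)` switches to
  the population denominator.
* **RMSSD** $= \sqrt{\sum_{i=2}^{n} (x_i - x_{i-1})^2 / (n - 1)}$,
  the mean taken over the $n-1$ successive differences.
* **pNN50** = percentage of successive differences *strictly* greater
  than 50 ms, again out of $n-1$. A difference of exactly 50 ms does not
  count. pNN50 is computed and reported for completeness but is not used
  by the quadrant rule or the model.

The **Baevsky-type stress index** is
$\mathrm{AMo} / (2 \cdot \mathrm{VR} \cdot \mathrm{Mo})$, computed from
a histogram of the intervals with 50 ms bins whose left edges sit at
multiples of the bin width starting from 0. Mo is the midpoint of the
modal bin in seconds, AMo the percentage of intervals in that bin, and
VR the max−min range in seconds. Ties between modal bins resolve to the
lowest bin, which makes the index deterministic. A constant series has
VR = 0 and the index is reported as an explicit error (or `NA` in
`hrv_summary()`), never as infinity. The anchored-at-zero binning is a
convention choice; any fixed anchor gives the same order of magnitude,
and the chosen one keeps bin edges independent of the data.

Artifact handling is deliberately minimal: `clean_rr()` applies a
plausibility window (default 300–2000 ms, **off by default**) and
reports the number of removals; there is no ectopic-beat interpolation.
All metrics operate on the series as given.

## Stroop scoring

A session is complete with exactly 35 responses. The score that feeds
the quadrant rule is the plain arithmetic mean RT over **all** trials,
errors included; weighting RT by accuracy is a separate research
question and is deliberately not the default (an optional
`correct_only = TRUE` mean is available). The 500 ms boundary is
strict-on-the-fast side: 499.9 ms is fast, 500.0 ms is slow. Responses
under 100 ms are flagged as anticipations in the log but never excluded.
Congruent and incongruent mean RTs are reported as descriptives only —
the quadrant rule and the model use the overall mean, so no
interference contrast is modelled.

The stimulus generator draws words uniformly from a fixed four-color
palette (red, green, blue, yellow), makes `round(n * congruent_prop)`
trials congruent (default 0.8 — color-word tasks of this kind are
typically congruent-heavy), pairs each incongruent word with a distinct
ink color, and shuffles. Everything is deterministic given the seed.

## SDNN norms and the deviation score

The normative SDNN is a lookup by age band. Bands are half-open
`[age_lo, age_hi)` with the final band closed, so every age in the
support maps to exactly one value and a boundary age belongs to the band
it opens. Outside the support the lookup raises — there is no silent
extrapolation. The deviation is `observed − normative`; strictly
positive deviations are *high*, everything else *low*. A deviation of
exactly zero therefore falls to *low* (only values above the norm count
as high); the `zero_as` argument flips this convention if a study
prefers the other reading.

The package ships only a clearly-labelled **synthetic placeholder**
table (`inst/extdata/sdnn_norms_synthetic.yaml`, round numbers spanning
ages 17–70, decreasing with age as published norms do). Normative SDNN
values differ across sources — short-term versus 24-hour recordings,
means versus medians — so the table is treated strictly as operator
data: load your own with `load_norm_table()` and record the provenance
in `source_label`.

## The quadrant table

`quadrant_table()` reports counts, valid percentages (one decimal) and
cumulative percentages in canonical order. Cumulative percentages are
computed from the **raw cumulative counts** and then rounded — not by
summing rounded row percentages — so the running total never drifts from
the raw data (with counts 186/370/150/169 the second cumulative value is
63.5, where summing rounded rows would give 63.6). Sessions missing
either measurement are excluded from the table and surfaced as an
explicit missing count, because attrition between the collected N and
the tabulated N must stay visible.

## The multinomial logistic model

With quadrant probabilities $\pi_k(x)$ and a reference category $r$
whose coefficient vector is fixed at zero,

$$\log \frac{\pi_k(x)}{\pi_r(x)} = \beta_{0k} + x^\top \beta_k, \qquad
  \pi_k(x) = \frac{e^{\eta_k}}{\sum_j e^{\eta_j}} .$$

Predictors enter untransformed (stress index, RMSSD ms, heart rate bpm,
AVNN ms, perceived food quality, female indicator, Epworth score, BMI,
hours awake) plus two age-band dummies (17–21 and 22–30, with >30 as
baseline). Coefficients are therefore per-unit-of-measurement log-odds,
and the printed odds ratio is `exp(beta)`.

**Reference category.** The default is `fast_high`. The design is
configurable because the choice only re-labels the log-odds: refitting
with a different reference reproduces the same predicted probabilities
(this invariance is tested to below 1e−6). A reference category cannot
have its own coefficient panel, so the default is the one quadrant for
which no panel is reported in the standard output layout.

**Fitting.** Full Newton iteration on the
reference-constrained log-likelihood, zero start, step-halving on the
(penalized) log-likelihood, convergence when the maximum absolute score
component falls below 1e−8 (or the parameter change below 1e−10), at
most 100 iterations. The observed information equals the expected
information for this model; its inverse provides the standard errors. A
singular information matrix is reported with the names of the collinear
columns. Under complete or quasi-complete separation the unpenalized
likelihood has no finite maximizer; the fitter detects the saturating
linear predictors (|η| > 20 on the data) and stops with advice to set
`ridge > 0`. The ridge penalty `ridge/2 · Σ slope²` (intercepts
unpenalized) guarantees a finite maximizer; reported log-likelihoods are
always unpenalized. Because the predictors are unstandardized, a given
`ridge` value is unit-dependent — it is a numerical stabilizer, not a
tuning parameter, and the default is 0.

**Fit statistics.** Nagelkerke's pseudo-$R^2$ is the Cox–Snell statistic
$1 - \exp\{(2/n)(\ell_0 - \ell)\}$ rescaled by its maximum
$1 - \exp\{(2/n)\,\ell_0\}$, so it is 0 for a model that does not
improve on the intercept-only fit and bounded by 1. The classification
table assigns each observation to its argmax probability (ties resolve
to the lowest category index) and the success rate is trace/total. Wald
statistics are $z^2 = (\beta/\mathrm{SE})^2$ with $\chi^2_1$ p-values;
reported significance uses three decimals with a 0.000 floor.

**Predictor importance.** A single global ordering is produced by the
maximum Wald statistic each predictor attains across the non-reference
equations, with dummy columns of one factor (the age bands) grouped as
one predictor. This summary rule is a documented package choice — other
defensible summaries (mean Wald, per-predictor likelihood-ratio tests)
would order near-ties differently.

**Missing data.** Complete-case analysis with an explicit exclusion
count; the pipeline reconciles input N = analyzed N + excluded N.

## The synthetic cohort generator

No public dataset exists for this pipeline, so the generator is
first-class, tested code that emulates the study conditions end-to-end:
63 participants, 10–20 app uses each (≈940 sessions), RR recordings of
300 beats (about four minutes at the default mean interval), cohort
SDNN target 55.2 ms, RR mean 844.7 ms, session mean RTs straddling the
500 ms cutoff (lognormal, median 480 ms), and covariates uniform over
age 17–69, BMI 16.4–31.4, 0–10 hours awake, Epworth 0–14, food-quality
1–5, with ~32% female participants.

RR series are stationary Gaussian AR(1) processes: the marginal SD is
the expected SDNN and the expected RMSSD is
$\mathrm{sd}\sqrt{2(1-\rho)}$, so the lag-1 autocorrelation $\rho$
decouples the two quantities the quadrant model uses. Two sources of
between-session heterogeneity are built in deliberately:

* $\rho$ is drawn per use from U(0.05, 0.9). A fixed $\rho$ would make
  RMSSD a deterministic multiple of SDNN across the whole cohort —
  a degeneracy real recordings do not show (short-term vagal structure
  varies between sessions) — and would leave the SDNN-based label
  quasi-separable from RMSSD alone.
* the per-use RR mean is drawn from N(844.7, 150) truncated to
  560–1400 ms, giving heart rate and AVNN realistic between-session
  spread; with a common mean the two would be numerically collinear
  over a few milliseconds of range.

Per-use SDNN varies lognormally around the cohort target (log-SD 0.35),
and values are redrawn into the 300–2000 ms window so synthetic series
always pass default cleaning. Labels are generated in two modes:
**pipeline mode** (default) runs every simulated use through the real
measurement chain — HRV summary, norm lookup, 500 ms rule — so
end-to-end behavior is tested; **model mode** samples labels from
softmax probabilities under a user-supplied coefficient matrix, which
isolates the fitter for parameter-recovery experiments. All randomness
descends from one master seed through a fixed splitting scheme
(`split_seed()`), so outputs are byte-identical per seed.

What the generator does **not** emulate: respiratory sinus arrhythmia
and circadian structure in HRV, RT learning/fatigue curves within a
session, and any dependence of the covariates on the physiological
state (covariates are drawn independently of the RR and RT processes
unless a coefficient matrix imposes structure on the labels). Passing
tests on synthetic cohorts therefore demonstrate the correctness of the
computations and the identifiability of the model under known
conditions — not physiological validity on real recordings. One
consequence worth knowing: because pipeline-mode labels are a
deterministic threshold of quantities correlated with the predictors,
cohort-level fits sit close to separation, which is visible as a high
pseudo-$R^2$ alongside a modest classification success rate (the Stroop
speed component is, by construction, unpredictable from the
covariates); a small ridge keeps such fits numerically stable.

## Numerical choices and test scales

* Newton tolerance 1e−8 on the score; parameter-change floor 1e−10;
  max 100 iterations; zero initialization makes fits deterministic.
* Softmax computations subtract the row maximum before exponentiating.
* Modal-bin ties → lowest bin; argmax ties in classification → lowest
  category index; zero SDNN deviation → low.
* Test problem sizes were chosen to keep the default suite fast while
  leaving comfortable statistical margins: oracle agreement on 1,000
  random series, fitter-versus-optimizer agreement on 20 datasets of
  120–200 rows, parameter recovery with 100 replicates at n = 2,000,
  AR(1) moment calibration at 50,000 beats, null p-value uniformity
  over 400 replicate fits.

## Known limitations

* The normative SDNN table is a placeholder; quadrant labels on real
  data are only as good as the norms supplied.
* Wald tests rely on the asymptotic normal approximation and are
  unreliable near separation (enormous odds ratios with enormous
  standard errors); the likelihood-ratio alternative is not implemented.
* The ridge stabilizer is unit-dependent because predictors are
  unstandardized; it is meant for numerical rescue, not shrinkage
  estimation.
* Frequency-domain and nonlinear HRV indices, ECG peak detection, and
  any clinical interpretation of the quadrants are out of scope.
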