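---
title: "Deriving pain-onset limits from censored threshold data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving pain-onset limits from censored threshold data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(painlimits)
```

## Purpose

`painlimits` implements a complete pipeline for deriving biomechanical
pain-onset limits for human-robot contact: from raw load-test signals,
through interval-censored threshold estimation, to quantile-based limit
tables for a target worker population. Because raw human-subject recordings
of this kind are not public, the package pairs the estimation pipeline with
simulators that generate synthetic trials with known ground truth, so every
stage can be validated end to end.

Two load cases are covered for each of 24 measured body locations:

* **quasi-static pinching** with an algometer (force ramped at a 1 mm/s
  deformation rate until the subject signals pain), and
* **dynamic impact** with a pendulum (stepwise-increasing impact velocity
  until the first painful trial).

Each is tested with a semi-sharp contact body (limits expressed as pressure,
N/cm²) and a blunt one (limits as force, N), giving four conditions per
location.

## The threshold model

Per-subject pain thresholds `y > 0` are modeled with an accelerated failure
time (AFT) law: covariates scale the threshold multiplicatively. With gender
as the single covariate (`x_G = 0` female, `1` male), the log-logistic
variant has CDF

```
F(y | x_G) = 1 / (1 + exp(-(log y - beta0 - x_G * beta1) / alpha))
```

* `beta0` — log-scale location for females,
* `beta1 >= 0` — log-scale gender shift (males tolerate more),
* `alpha > 0` — shape (spread on the log scale).

Because the covariate enters only through the linear predictor, `x_G` may be
set to a *fraction* to describe a mixed group: `x_G = 0.7` represents a
70%-male worker population. The quantile function inverts in closed form:

```{r}
loglogistic_quantile(0.75, beta0 = 4.22, beta1 = 0, alpha = 0.46, x_G = 0.7)
```

Weibull and log-normal alternatives are available through the same
standardized-quantile interface; `select_family()` picks among the three by
the Anderson-Darling statistic of the probability-integral-transformed
sample, with ties broken toward the log-logistic.

## From raw trials to a sample

**Pinching.** The algometer signal is a 100 Hz force ramp. Conditioning:
low-pass filter (channel class CFC1), baseline offset elimination with
contact-onset detection (first run of 5 samples above
`max(5 x baseline SD, 0.5 N)`), and the maximum force norm up to the
subject's switch-press event. The observation is treated as exact.

**Impact.** The pendulum signal is a 10 kHz tri-axial recording per trial.
Conditioning: CFC100 filtering, offset elimination, inertia compensation
(the load cell under-reads the contact-tip force by `V_f = 1 + m_I/m_B`,
where `m_I` is the contact-body mass and `m_B` the pendulum-body mass), and
the global maximum of the force norm. A staircase of such trials yields an
*interval-censored* observation: the threshold lies between the penultimate
(no-pain) peak `L` and the final (painful) peak `R`. A first-trial pain
response is fully left-censored (`L = 0`); reaching the 1.25 m/s velocity
cap without pain is right-censored (`R = Inf`).

**Pressure fields.** For semi-sharp conditions the measurand is the peak
pressure of an 8-bit pressure-film recording (2.07 kHz, 0-1200 N/cm² range,
14 x 14 sensels on the 1.96 cm² face). Conditioning order is fixed:
per-view 3x3 Gaussian blur (variance `2/pi`, lateral views first scaled by
the edge projection factor), periodic cubic-spline interpolation of the
blind corner spots along each closed sensel contour, then calibration of the
pressure integral to the simultaneously measured contact force. Calibrating
*last* guarantees force conservation regardless of earlier smoothing.

Censored observations are midpoint-imputed (`(L+R)/2`; `R/2` when
left-censored; `L` when right-censored), repeats are averaged per subject
(pooled over the two pendulum masses), and `assemble_sample()` applies the
structural rules of the study design (no neck-muscle measurements; the
pectoral location is male-only).

## Estimation and the gender rule

`fit_aft()` maximizes the likelihood over `(beta0, beta1, log alpha)` with a
quasi-Newton method and five deterministic multi-starts seeded from moment
estimates; the covariance is the inverse observed information mapped back to
the `alpha` scale. Two fitting modes are provided:

* `mode = "exact"` (default): the midpoint-imputed subject means are treated
  as exact observations. This mirrors the descriptive pipeline order
  (impute, then average, then fit).
* `mode = "interval"`: the censored-data likelihood is evaluated on the
  per-subject *mean* intervals. Averaging before fitting is deliberate:
  repeats of one subject share that subject's threshold, so entering them as
  independent intervals would overstate the information in the sample.

Gender is kept for a body location only when its Wald test is significant
(`p < 0.05`) in at least two of the location's conditions; otherwise the
location is refitted with `beta1 = 0`. Fit quality is summarized by a
quantile-quantile R²: the squared correlation between the sorted
gender-adjusted subject means and the model quantiles at plotting positions
`(i - 0.5)/N`.

## Limits

The proposed limit for a condition is the 75th-percentile threshold of a
70%-male group, `quantile_limit(fit, q = 0.75, x_G = 0.7)`, with
delta-method confidence intervals on the linear predictor
(`quantile_ci()`). `round_for_standard()` rounds to the nearest 10 (half
away from zero) and appends the untested neck muscle as 1.2 x the temple's
rounded limits — an estimate justified by the similarity of the two
locations' threshold distributions in earlier algometry work, and flagged
`estimated` in the output.

Comparison utilities quantify structure across conditions and studies:
`relative_difference()` (impact limits average about 1.8 x the pinching
limits for the blunt contact), `relative_deviation()`
(`epsilon = 1 - reference/own`) against reference studies, and
`pearson_k()` for the force-pressure correlation of pressure-based
measurands.

## What the simulators do and do not emulate

The generators reproduce the *measurement process*: ramp and pulse shapes,
sampling rates, sensor offset and Gaussian noise, 8-bit film quantization,
staircase termination rules, inertia scaling, and ground-truth thresholds
drawn from the expanded law. The contact stiffness used by the simulators is
not a tissue-mechanics claim; it is chosen per condition so that staircases
terminate inside the protocol's velocity range (the heavy pendulum reaches
the median threshold near 0.4 m/s). Subject-level covariates other than
gender (age, height, weight) are generated for realism but have no effect on
thresholds. Physiological effects such as habituation, spatial summation, or
between-session drift are out of scope.

Default problem sizes follow the study design (group rosters of 11-41
subjects; 96 location x condition cells); they are configuration defaults of
this package, not constraints of the method, and `pipeline_config(scale =)`
shrinks them for quick runs.

## Numerical choices

* Channel-class filtering uses a -3 dB cutoff of 1.65 x the class value
  (CFC1 = 1.65 Hz, CFC100 = 165 Hz), realized as a two-pass 2nd-order
  Butterworth: net 4th order, zero phase, unity DC gain; edges are
  odd-reflection padded.
* Optimization tolerance is `reltol = 1e-12`; multi-start offsets are fixed,
  so fits are deterministic given the sample.
* All simulator randomness is scoped with `withr::local_seed`, and the
  pipeline derives one seed per location x condition cell from the root
  seed, so full runs are bit-reproducible.
* Quantile/CDF round-trips hold to 1e-9 across the entire published
  parameter table (see the acceptance test suite).

## Limitations

Midpoint imputation biases the spread downward when intervals are wide
relative to the threshold distribution; the interval likelihood mode is the
statistically cleaner alternative but was not the source of the published
parameter table, so the package keeps exact-on-imputed as the default.
Right-censored staircases contribute only a lower bound; in exact mode their
imputed value (`L`) understates the threshold. The delta-method intervals
are asymptotic and can undercover in the smallest cells (11 subjects).
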