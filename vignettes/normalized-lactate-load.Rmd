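---
title: "Normalized lactate load: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized lactate load: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactload)
```

## The statistic

A single lactate value is a static snapshot of the balance between lactate
production and clearance; the quantity associated with organ injury is the
*cumulative* burden of hyperlactatemia — how high, and for how long. For a
patient with lactate values $Lac_0, Lac_1, \dots$ at times
$T_0, T_1, \dots$ (hours since ICU admission) inside an observation window
$[0, W]$ (default $W = 24$ h), the package defines

$$\text{lactate load} \;=\; \sum_i \frac{Lac_{i+1} + Lac_i}{2}\,(T_{i+1} - T_i)
\quad [\text{mmol·h/L}],$$

the trapezoidal area under the piecewise-linear lactate–time curve, and

$$\text{normalized lactate load} \;=\; \frac{\text{lactate load}}{W}
\quad [\text{mmol/L}],$$

the time-weighted average lactate over the window. Because lactate is not
measured exactly at the window edges, the curve is extended by carrying the
first observed value back to $t = 0$ and the last observed value forward to
$t = W$ (`extend_to_window()`). The normalized load is therefore always
bracketed by the minimum and maximum observed values, and equals the
constant for a constant series.

Alongside it the package computes the two conventional static summaries,
maximum lactate and the *unweighted* arithmetic mean of the raw
measurements. The mean is deliberately not time-weighted — otherwise it
would duplicate the normalized load; the contrast between the two is
exactly what the downstream ROC comparison examines.

## Ingest conventions

Three situations are not fixed by the definition above and are resolved as
follows:

* **Duplicate timestamps** (two draws charted at the same time) are
  averaged into a single curve point at ingest. The trapezoid rule needs a
  function of time; averaging is symmetric and order-independent.
* **Pre-admission draws** (negative times) are dropped, with the count
  retained in the series' `n_dropped` attribute: the analysis is defined on
  the first $W$ hours of the ICU stay.
* **Draws after the window end** are dropped rather than interpolated
  back, so the value at $t = W$ is the last value observed *within* the
  window.

Units are fixed: mmol/L and hours. There is no unit-conversion layer and no
imputation of missing measurements.

## Eligibility cascade and cohorts

`apply_exclusions()` screens a patient table with four sequential criteria:
age < 18 years; not the first ICU admission; fewer than two in-window
lactate measurements; ICU stay shorter than 24 h. Each patient is counted
at the *first* criterion it fails, which makes the per-step counts of the
filter report reproducible (any consistent attribution would satisfy the
totals; the fixed printed order is chosen for determinism). "Fewer than
two" deliberately covers patients with zero measurements. Included patients
are then split by the supplied Sepsis-3 flag (`split_by_sepsis()`) — the
package treats sepsis adjudication as an input attribute, never something
it derives.

## ROC and DeLong machinery

All three markers are oriented so that **higher values indicate higher
28-day mortality risk**; there is no automatic direction detection.

* `auc_mann_whitney()` is the standard nonparametric AUC with half-credit
  for ties — the estimator the DeLong variance theory presupposes.
* `delong_components()` exposes the structural components (placements):
  per-positive and per-negative tie-corrected exceedance fractions, whose
  sample variances give $\widehat{var}(AUC) = S_{10}/m + S_{01}/n$.
* Paired comparisons (two markers on the same patients) subtract twice the
  placement covariance; unpaired comparisons (disjoint cohorts) set the
  covariance to zero. Both refer $z$ to the standard normal, two-sided.
  (pROC, used as an independent cross-check in the test suite, refers its
  *unpaired* statistic to a t distribution instead; the statistics agree
  to numerical precision, the p-values differ accordingly.)
* The AUC confidence interval is Wald on the probability scale, truncated
  to $[0,1]$ — the simplest defensible construction. A zero-variance
  degenerate case yields the degenerate interval.
* `youden_cutoff()` returns the observed score maximizing
  $J = \text{sens} + \text{spec} - 1$ under the "positive if score ≥
  cutoff" convention, ties broken toward the smallest cutoff. The cutoff
  selection rule and the CI construction are declared package choices, not
  properties of the statistic.
* `operating_characteristics()` reports the 2×2 table at a cutoff with
  Clopper–Pearson exact intervals for sensitivity, specificity and the
  predictive values (at observed prevalence), and log-method intervals for
  the likelihood ratios. A likelihood ratio with a zero denominator is
  reported as infinite with a one-sided interval and logged.

All intervals default to 95%; two-sided $\alpha = 0.05$.

## Descriptive comparisons

`table_one()` follows common clinical-reporting practice: a one-sample
Kolmogorov–Smirnov test against a normal with *estimated* mean and SD
(a Lilliefors-flavored usage; the reference parameters are a package
choice) gates, at $\alpha = 0.05$, between mean ± SD with Student's
t-test and median (IQR) with the Wilcoxon rank-sum test. Categorical
variables use Pearson's chi-square without continuity correction. Samples
with $n < 3$ or zero variance are treated as non-normal. No
multiple-testing correction is applied. Summaries are formatted to one
decimal by default (configurable); all underlying numbers are kept at full
precision, rounding happens only at the presentation layer.

## The synthetic cohort generator

Access to large critical-care databases is restricted, so the package
ships a generator (`generate_cohort()`) that emulates the *shape* of such
data well enough to exercise every pipeline step:

* **Trajectory**: each patient has a latent exponential decay toward a
  baseline, $Lac(t) = b + (L_0 - b)e^{-kt}$ — the simplest clinically
  plausible kinetic for early-ICU lactate. Its exact time average over the
  window (`true_normalized_load()`) is the ground truth that the observed
  normalized load estimates.
* **Sampling**: measurement times are uniform on the window; values get
  Gaussian noise (truncated at 0.1 mmol/L). Sampling is denser in sepsis.
* **Outcome**: 28-day death is Bernoulli with
  $\text{logit}^{-1}(\beta_{0,\text{group}} + \beta_1 \cdot
  \text{true normalized load})$, $\beta_1 > 0$.
* **Ineligible records** (minors, repeat stays, forced single-measurement
  patients, short stays) are injected at configurable rates so the
  exclusion cascade has work to do.

Default parameters (group sizes 20% sepsis; initial lactate lognormal with
medians ≈ 3.0 vs 2.4 mmol/L; clearance medians 0.05 vs 0.10 h⁻¹; sampling
intensities 5 vs 3.5 draws/24 h; noise SD 0.5 vs 0.4 mmol/L; intercepts
−2.9 / −3.6 and slope 0.9 per mmol/L, giving ~37% vs ~12% mortality) were
chosen once to echo the qualitative contrasts reported for real ICU
cohorts — higher lactate, slower clearance, denser sampling and higher
mortality in sepsis. This is qualitative calibration only; the generator
makes no claim of matching any database's empirical distributions, and
passing tests on it demonstrate correctness of the *machinery*, not
clinical performance on real data. Real EHR features it does not emulate:
informative sampling (sicker patients measured more), treatment feedback
(resuscitation responding to lactate), non-monotone trajectories, charting
artifacts.

One reconciliation between two generator contracts: the standalone
`sample_measurements()` draws counts as $1 + \text{Poisson}(\lambda - 1)$,
but `generate_cohort()` must guarantee that setting every ineligibility
rate to zero leaves the cascade with nothing to remove — impossible if
natural Poisson singletons can occur, since a single measurement is itself
an exclusion criterion. The cohort generator therefore draws non-forced
counts as $2 + \text{Poisson}(\lambda - 2)$ (expectation ≈ $\lambda$,
minimum 2), so single-measurement patients arise only through the
configured rate.

All randomness flows from one seed in the config; `run_analysis()` itself
is fully deterministic, so identical simulate + run invocations produce
byte-identical report CSVs.

## What the simulation tests establish

Under the defaults, at a cohort size of 20,000 screened patients:

* the AUC ordering **normalized load ≥ mean ≥ max** emerges, because the
  outcome is driven by the true time-averaged burden, which the
  trapezoidal estimate tracks best, the unweighted mean tracks with more
  variance, and the maximum tracks worst (it chases the initial value plus
  noise extremes);
* non-survivors have higher normalized load than survivors in both sepsis
  strata;
* stratifying the non-sepsis cohort by minimum measurement count
  (≥2, ≥3, ≥4, ≥5) yields AUCs that are non-decreasing up to simulation
  error (the suite allows 0.02, roughly two Monte-Carlo SDs at the
  smallest stratum), since with noise and sparsity as the only error
  source, more measurements mean a better estimate of the true burden.

## Numerical choices and problem sizes

Quadrature oracles in the tests integrate the piecewise-linear interpolant
on a 10⁻⁴-h grid augmented with the knots (making the oracle exact);
agreement is required to 10⁻⁶ mmol·h/L over 1,000 random series. AUC and
Youden results are checked against exhaustive $O(mn)$ oracles on instances
up to $n = 200$. DeLong SEs are compared with a 2,000-replicate bootstrap
at $n = 500/500$ (10% relative tolerance); type-I error of both tests is
checked over 2,000 null replicates at $n = 200/200$ against the 99%
binomial band around 0.05; interval coverage over 500 replicates. The
end-to-end properties use a single 20,000-patient cohort. These sizes keep
the whole suite under two minutes on one CPU while leaving Monte-Carlo
error well inside the asserted tolerances.

Known limitations: the statistic cannot distinguish rising from falling
lactate patterns with equal areas; boundary extension biases the load when
the first draw is late in a fast-evolving trajectory; the generator's
measurement-count mechanism is independent of severity, unlike real ICUs
where sampling is informative.
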