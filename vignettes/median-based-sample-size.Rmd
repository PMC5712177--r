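---
title: "Median-based sample size for log-normal outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-based sample size for log-normal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lognsize)
```

## The model and its assumptions

Many health outcomes — operative times, lengths of stay, costs, biomarker
concentrations — are positive and right-skewed, and are analysed after a
natural-log transformation with a two-sample t-test.  Planning such a study
requires a mean difference and variances *on the log scale*, which clinical
teams rarely have.  What they can usually state is, per arm, a median $m_j$
and an untransformed standard deviation $\phi_j$, in the outcome's own
units.

`lognsize` assumes the outcome in arm $j$ is log-normal,
$\log T \sim N(\mu_j, \sigma_j^2)$.  Two identities then carry the
raw-scale elicitation onto the log scale:

* the median equals the geometric mean, $m_j = e^{\mu_j}$, so
  $\tau = \mu_1 - \mu_2 = \log m_1 - \log m_2$;
* the raw variance is $\phi_j^2 = m_j^2\, x (x - 1)$ with
  $x = e^{\sigma_j^2}$, a quadratic in $x$ whose positive root gives
  $$\sigma_j^2 = \log\!\left(\tfrac12 + \sqrt{\tfrac14 + \phi_j^2 / m_j^2}\right).$$

The conversion depends on $(m_j, \phi_j)$ only through the coefficient of
variation $\phi_j/m_j$ (`log_scale_variance()` is exactly scale invariant),
is zero iff $\phi_j = 0$, and is inverted by `raw_variance_from_log()`; the
test suite checks the round trip to $10^{-10}$ relative tolerance over a
randomised grid of medians in $[0.01, 1000]$ and SDs in $[0, 100]$.  All
logarithms are natural throughout.

The per-group size is the standard normal-approximation formula
$$n = \frac{(\sigma_1^2 + \sigma_2^2)(z_{\alpha/2} + z_\beta)^2}{\tau^2}.$$

Note that equal raw SDs in the two arms do **not** imply equal log-scale
variances when the medians differ — each arm gets its own $\sigma_j^2$.

## Parameters, units, defaults

| parameter | meaning | default |
|---|---|---|
| `median`, `sd` (`group_spec`) | per-arm median and raw SD, outcome units | — (must be given) |
| `alpha` | two-sided significance level | 0.05 |
| `power` | target power $1-\beta$ | 0.9 |
| `z_alpha`, `z_beta` | quantile overrides | `NULL` (exact `qnorm`) |
| `pad` | extra subjects per group after rounding | 0 |
| `icc`, `cluster_size` (`cluster_spec`) | intra-class correlation, average cluster size | — |
| `n_reps` | Monte-Carlo replicates | 100000 |

Exact double-precision quantiles are the default because they reproduce
every analytic size in the built-in scenario sets; the overrides exist for
calculations done with the conventional rounded values 1.96 and 1.28, as in
the clustered surgical example (`lognsize_cli("worked-example")`), where the
rounded quantiles give the continuous size 30.18.

`pad` implements the usual small-sample caution: the formula uses normal
rather than t quantiles, so at small n the t-test runs one or two subjects
short of nominal power; adding one or two per group compensates.

## Numerical and rounding choices

* **Rounding is always up** (ceiling), per group, before anything else uses
  the integer size.
* **Clustering order of operations**: the design effect
  $1 + \mathrm{ICC}(m - 1)$ multiplies the already rounded (and padded)
  per-group n, the product is re-ceiled to whole observations, and the
  cluster count is the ceiling of observations over average cluster size.
  With 32 observations, ICC 0.2 and clusters of 10: $2.8 \times 32 = 89.6
  \to 90$ observations in $\lceil 90/10 \rceil = 9$ clusters.
* **Lower clamp at 2 per group**: a two-sample t-test needs at least two
  observations per arm, so extreme inputs (huge $\tau$, tiny variances)
  never return a meaningless n of 0 or 1.
* **Degenerate inputs**: `sd = 0` is a valid point-mass description and is
  accepted by all conversions; the sizing functions reject designs whose
  log-scale variances are *both* zero ($n$ would be 0) and reject
  $\tau = 0$ ("no detectable difference") rather than returning infinity.
* Equal medians with `sd = 0` draws produce constant samples; the test
  runner defines two equal constant samples to retain the null and two
  distinct constant ones to reject, instead of failing inside the test
  statistics.

## The exponential sensitivity analysis

A skewed outcome need not be log-normal.  For exponential data the median
determines the rate, $\lambda_j = \log 2 / m_j$, and the SD is
$1/\lambda_j$, so the log-normal conversion assigns every exponential
median/SD pair the same log-scale variance
$\log(1/2 + \sqrt{1/4 + 1/\log^2 2}) \approx 0.7065$.  The true variance of
a log-exponential variable is $\pi^2/6 \approx 1.645$ — more than twice as
large — so the log-normal formula under-sizes badly;
`n_exponential_naive()` exposes that failure, and `n_exponential()` sizes
correctly by substituting $\pi^2/6$ for both arms.  The engine's
exponential family lets both choices be verified by simulation
(`replicate_table(2)` and `replicate_table(3)`).

## The Monte-Carlo engine

Each replicate draws $n$ values per arm — `rlnorm(n, log m_j, σ_j)` or
`rexp(n, log 2 / m_j)` — and applies three two-sided tests at level
$\alpha$: a t-test on the log values, a Mann-Whitney U test on the raw
values, and a t-test on the raw values.  Rejection proportions are reported
with their Monte-Carlo standard errors $\sqrt{p(1-p)/N}$.

Design choices that were genuinely open:

* **t-test variant.** Pooled-variance Student's t is the default, matching
  the classical formula the sizing is derived from; a Welch option is
  provided.  At the scenario sizes the two are indistinguishable relative
  to Monte-Carlo error.
* **Mann-Whitney p-value.** The default follows standard statistical
  software practice: exact enumeration when both groups have fewer than 50
  observations and there are no ties, otherwise the normal approximation
  with continuity correction.  This matters: at n = 14 per group the
  corrected approximation is conservative enough to depress estimated power
  by roughly two percentage points, visibly below published estimates of
  rank-test power at small n, while the exact test agrees with them.
  `mw_exact = TRUE/FALSE` forces either method.  Ties have probability zero
  under both families, so the exact path is the realistic small-n default.
* **Seeding.** Streams are keyed by a small integer hash of
  `(seed, replicate, group)`, so a replicate can be redrawn in isolation,
  results do not depend on execution order, and the whole table is
  reproducible from one seed.  The caller's RNG state is saved and
  restored.  Row seeds in `replicate_table()` derive from the master seed
  through the same hash.

## What the generator emulates — and what it does not

The synthetic samples are *exactly* log-normal (or exponential): no
measurement error, no censoring or truncation, no mixture structure, no
within-cluster correlation, and independent observations throughout.
Passing tests therefore demonstrate that the formula, the conversions and
the three tests behave as claimed **under the stated distributional
model**.  They say nothing about robustness to distributions other than
the two implemented families — the exponential results show how consequential
that caveat can be — and the clustering adjustment is the analytic design
effect only; clustered data are never simulated, so the ICC must come from
external knowledge.

## Problem sizes used by the test suite

The package's own tests replicate the built-in scenario sets at reduced
replicate counts — 10000 replicates for the headline power comparisons,
1000–4000 for calibration and ordering properties — with acceptance bands
of three Monte-Carlo standard errors at the count actually run.  Full
fidelity (100000 replicates, the default `n_reps`) is a matter of minutes
per scenario from the CLI: `tables --id 1 --reps 100000`.  Distributional
spot checks (sample median, variance, and the $\pi^2/6$ constant) use
$10^6$ draws against three-standard-error bands computed from the drawn
sample's own moments.

## Known limitations

* Two groups only; no survival/censoring, no non-inferiority margins, and
  no distribution families beyond log-normal and exponential.
* The unequal-allocation function is the standard allocation-ratio
  generalisation of the equal-allocation formula, provided as a
  convenience extension rather than a separately validated method.
* The design-effect adjustment presumes a common average cluster size and
  an externally estimated ICC; variable cluster sizes and drop-out
  inflation are protocol-level choices left to the analyst.
* As with any normal-approximation formula, sizes below roughly 15 per
  group run slightly under nominal power for a t-test; use `pad`.
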