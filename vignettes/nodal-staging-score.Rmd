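---
title: "Nodal staging scores for pN0 esophageal squamous cell carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nodal staging scores for pN0 esophageal squamous cell carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalstaging)
```

## The problem

A patient resected for esophageal squamous cell carcinoma is staged
pN0 when none of the examined lymph nodes contains tumor. That label
depends on how many nodes were examined: with three nodes harvested, a
missed metastasis is plausible; with forty, it is not. This package
quantifies that dependence. For each T stage it estimates the
probability that a pN0 diagnosis is a false negative, corrects the
stage's lymph-node-metastasis (LNM) rate for the patients it estimates
were missed, and converts both into a *nodal staging score* (NSS): the
posterior probability that a pN0 patient with `e` examined nodes is
truly node negative. Inverting the score gives the minimum
lymphadenectomy extent needed for a target confidence, e.g. 90%.

## The model

Three assumptions drive everything:

1. there are no false node-positive patients — a pN0 label can be
   wrong, a pN+ label cannot;
2. within a patient, every lymph node is equally likely to be involved,
   so only the number of examined nodes matters (node location is
   deliberately ignored);
3. within a T stage, latent LNM prevalence is homogeneous.

Among node-positive patients of one T stage, the count `m` of positive
nodes among `e` examined is modelled as beta-binomial,

$$P(m \mid e) = \binom{e}{m}
  \frac{B(\alpha + m,\; \beta + e - m)}{B(\alpha, \beta)},$$

a binomial whose per-node involvement probability is drawn per patient
from a Beta(α, β) — the between-patient heterogeneity in nodal burden
that a plain binomial misses. The probability that a patient with
latent metastasis shows *no* positive node among `e` examined is the
mass at zero,

$$P(\mathrm{FN} \mid e) = \frac{B(\alpha,\; \beta + e)}{B(\alpha, \beta)},$$

which equals 1 at `e = 0` and decreases strictly in `e`. At each
observed `e`, the expected number of false-negative pN0 patients is
estimated from the observed node-positive count `TP_e` by the odds
identity

$$FN_e = \min\!\Big(\frac{P(\mathrm{FN}\mid e)}{1 - P(\mathrm{FN}\mid e)}
  \, TP_e,\; N_e\Big),$$

capped at the number `N_e` of pN0 patients actually available to
reclassify. Summing over `e` gives the adjusted LNM rate

$$\mathrm{rate} = \frac{\sum_e FN_e + \sum_e TP_e}
  {\sum_e N_e + \sum_e TP_e} \;\ge\; \text{raw rate},$$

and the score is the Bayes posterior

$$\mathrm{NSS}(e) = \frac{1 - \mathrm{rate}}
  {(1 - \mathrm{rate}) + \mathrm{rate} \cdot P(\mathrm{FN} \mid e)},$$

which starts at the prior `1 - rate` at `e = 0` and increases strictly
to 1. `adequate_lne()` returns the smallest `e` whose score strictly
exceeds the threshold (default 0.90, matching the "over 90% truly pN0"
convention; `strict = FALSE` switches to `>=`, and a 1e-9 numerical
guard keeps exact-boundary scores from being reclassified by
floating-point noise).

## Fitting: why the likelihood is conditioned

The shape pair is estimated by maximum likelihood from the
node-positive patients of a stratum, after excluding patients whose
examined nodes were *all* positive (`m = e`): for them the
false-negative probability is identically zero and more sampling could
only have raised the count, so they carry no usable information about
the distribution's lower tail (they still count in `TP_e`).

The fitting set is therefore not a random sample from the
beta-binomial: it is conditioned on `1 <= m <= e - 1`. `fit_betabinom()`
maximizes the correspondingly conditioned likelihood by default
(`conditioning = "observed"`), dividing each patient's pmf term by the
observable-window mass `1 - P(m = 0) - P(m = e)`. Ignoring the
conditioning (`conditioning = "none"`, also the default of the plain
`betabinom_loglik()` sum) systematically overstates the mean
involved-node fraction — in our simulations at realistic shapes the
unconditioned fit returned a mean fraction of about 0.23 when the
truth was 0.15, deflating the false-negative probabilities and with
them the entire downstream correction. The conditioned fit recovers
the generating shapes, which is what makes the package's end-to-end
consistency checks (below) possible. Both objectives are exposed so
the difference can be reproduced in one line.

Numerics: optimisation runs on `(log alpha, log beta)` with L-BFGS-B
bounded to `[1e-4, 1e4]` per shape, started from method-of-moments on
the `m/e` fractions (clipped to `[0.01, 100]`, falling back to `(1,1)`
when the moments degenerate), objective tolerance near machine
precision, and a large negative sentinel instead of `-Inf` when a term
underflows. Strata with fewer than two usable pairs raise an error
suggesting pooling rather than returning a silent non-fit.

## Uncertainty

`bootstrap_statistics()` resamples patients with replacement within
each T stratum — pN0 and pN+ jointly, preserving stratum size — and
refits the shapes and recomputes raw rate, adjusted rate, and their
difference on every replicate; 1000 replicates mirrors the precision
analysis the score methodology was published with. Intervals are
percentile (2.5/97.5): simple, seed-auditable, and adequate for the
smooth statistics involved, at the cost that a skewed statistic's
interval may exclude its point estimate (reported as a warning, never
hidden). The increase interval is formed from per-replicate
differences, not interval arithmetic, so it respects the
adjusted-at-least-raw constraint replicate by replicate. A master seed
spawns one sub-seed per replicate, making results independent of
evaluation order; replicates whose fit fails are dropped and counted,
and more than 10% failures is a hard error.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` generates cohorts under exactly the three model
assumptions: latent metastasis is Bernoulli(prevalence) per stage;
examined-node counts follow a negative binomial shifted to support
`>= 1`; latent-positive patients draw `m` from the unconditional
beta-binomial, so draws of `m = 0` *are* the false-negative pN0
patients (a zero-truncated alternative, `m_convention = "truncated"`,
produces a world with no false negatives for sensitivity checks);
survival is exponential with a hazard set by the *latent* status plus
independent exponential censoring, so false-pN0 patients carry
node-positive mortality — the mechanism by which a higher score should
predict better survival.

Defaults are chosen to resemble the published cohorts: per-stage
prevalences (0.24, 0.40, 0.51, 0.71) near the reported adjusted rates;
shapes `alpha = 0.8`, `beta = 4.5` giving a mean involved-node
fraction of about 0.15 with strong overdispersion, consistent with a
median of 2 positive nodes among a median of about 13 examined;
examined-node distribution `1 + NB(size 2.2, mean 12)` matching a
median near 12 with a 6-19 interquartile range (the
institution-flavoured preset uses mean 18, median near 19). Hazards
(0.010 vs 0.030 per month, censoring 0.015) give the few-year
disease-specific survival separation seen in registry data.

The generator reproduces the model's world, not the real one: no node
stations or location effects, no covariate-driven prevalence
heterogeneity within a stage, no cure fraction or non-proportional
hazards, and examined-node counts independent of latent status.
Passing tests therefore demonstrate internal consistency of the method
and correctness of the implementation — not that the three assumptions
hold in any real cohort.

## Fixtures that resemble the published tables

`make_fixture_table()` writes small synthetic CSVs whose *marginal
counts* mirror the two published cohorts — per-stage pN0/pN+ sizes
171/39, 169/69, 340/211, 125/146 (registry-flavoured) and 116/34,
117/171-style splits for the institutional preset — so the raw-rate
arithmetic of the published tables (e.g. 39/210 = 0.186,
661/1404 = 47.1%) is reproduced exactly while every patient remains
synthetic. Two published count sets disagree internally (the text
reports an overall registry split of 795/454 while the characteristics
table implies 805/465, and the overall 35.5% rate follows from
neither); the fixtures follow the per-stage table. Printed values that
require the real patient-level data — the fitted shape parameters, the
adjusted-rate point estimates, the published adequate-extent tables
(which themselves disagree between the results text and the summary
table), and the absolute 5-year survival percentages — are documented
but not asserted anywhere.

## Verification by survival

`validate_survival()` scores the pN0 patients, groups them by score
quartiles (pooled across stages by default; the within-stage variant
is an argument, since the published grouping does not say which was
used), and compares groups with Kaplan-Meier curves and a log-rank
test via the survival package. Quartile ties go deterministically to
the lower group — the score takes one value per examined-node count
within a stratum, so boundary ties are routine. Cox regression and
spline analyses on real covariates are out of scope here: they
validate findings on data this package does not ship, whereas the
KM/log-rank direction check is exercisable on the generator.

## Problem sizes used by the checks

The test-suite calibrations are simulation-design choices: shape
recovery uses 2000 observed pN+ pairs (mean involved-node fraction
within 0.02 of truth); the brute-force likelihood grid is 200x200
log-spaced over `[0.01, 100]^2`; end-to-end adjusted-rate recovery
uses cohorts of 10 000 patients per stratum with the deviation
averaged over 5 replicates, against a 0.02 tolerance — the averaging
separates the method's bias (none detectable) from single-cohort
Monte-Carlo noise (standard deviation near 0.015 at this size, partly
intrinsic to the odds-weighted small-`e` cells of the false-negative
estimator); bootstrap coverage uses 100 cohorts of 2000 patients with
200 replicates each; the survival direction check uses 2000 patients
in the test suite and 6000 in the reproduction script (the log-rank
test has about 85% power at 2000 under a tenfold latent-hazard
separation, so the larger size gives a stable measurement of the
direction property).

## A worked example

```{r example}
cfg <- synthetic_config(n_patients = 2000, seed = 7)
sim <- simulate_cohort(cfg)
fits <- fit_cohort(sim$cohort)
rates <- cohort_adjusted_rates(sim$cohort, fits)
for (r in rates) print(r)

# minimum examined nodes for 90% confidence in pN0, per stage
vapply(as.character(1:4), function(t) {
  adequate_lne(rates[[t]]$adjusted_rate, fits[[t]]$alpha, fits[[t]]$beta)
}, 0L)
```

## Known limitations

The equal-involvement and within-stage-homogeneity assumptions are
biologically wrong (the method's own framing concedes this); scores
are only as good as the stratum fit, and sparse strata (few pN+
patients, or all-positive patterns) refuse to fit by design; the
false-negative count estimator is noisy where few nodes were examined,
because small-`e` cells enter with large odds weights; and percentile
bootstrap intervals can undercover for extreme shape parameters even
when rate intervals are well calibrated.
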