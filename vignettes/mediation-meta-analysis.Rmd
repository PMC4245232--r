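---
title: "Decomposing animal-study effects: the mediation model and its pooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing animal-study effects: the mediation model and its pooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediameta)
```

## The question and the model

A typical neurogenesis experiment shows that an intervention (running
wheels, irradiation, stress, a transgene) changes both hippocampal
neurogenesis and behaviour, and concludes that the first caused the
second. That inference skips over every other consequence of the
intervention. The model implemented here separates the two routes. For a
two-group study with treatment indicator $T \in \{0, 1\}$, standardised
mediator $M$ (e.g. BrdU$^+$ or Ki67$^+$ cell counts) and standardised
behavioural outcome $Y$:

$$M = \alpha_M + \beta_1 T + \varepsilon_M, \qquad
  Y = \alpha_Y + \beta_3 M + \beta_4 T + \varepsilon_Y,$$

with independent normal errors. The **indirect effect** is the product of
coefficients $\beta_1 \beta_3$ — the part of the treatment effect
transmitted through the mediator. The **direct effect** $\beta_4$
collects every other mechanism. The **total effect** is their sum, and
`percent_mediated()` reports $100\,\beta_1\beta_3 / (\beta_1\beta_3 +
\beta_4)$.

Assumptions worth stating plainly: the relationships are linear with a
common mediator slope in both groups; behavioural testing does not itself
alter the mediator differentially between groups; and there is no hidden
variable that both tracks the mediator and drives behaviour. The last
cannot be checked from these data — a small indirect effect is evidence
*against* the mediator mattering, but a large one is necessary, not
sufficient, evidence for it. Studies with a strong group-by-mediator
interaction violate the common-slope assumption;
`within_group_association()` flags them (interaction t-test at p < 0.05)
rather than modelling them.

## Pre-fit transformations

* **Standardisation** (`standardize()`): mediator and outcome are z-scored
  with the $n-1$ sample SD, *pooled across both groups within a study*.
  Pooled, because per-group standardisation would erase the very group
  difference $\beta_1$ the model estimates; within-study, so that effects
  from different assays and tasks share a standard-deviation scale and can
  be pooled across studies.
* **Bounded outcomes** (`logit_percent()`): percent-scale outcomes (e.g.
  percent time freezing) are mapped through $\log(p/(1-p))$ with
  $p = \text{value}/100$ *before* standardisation, so the normal linear
  model cannot predict impossible values. Exact 0% or 100% is rejected by
  default; an explicit opt-in clamp to $[\varepsilon, 1-\varepsilon]$
  (default $\varepsilon = 0.005$) exists because silent clamping can bias
  estimates and should be a visible analyst decision.
* **Orientation** (`orient_effects()`): for tasks where lower scores mean
  better performance (escape latency, immobility time), effect draws are
  negated *after* fitting, at the estimate level, so positive always means
  better. Data are never modified, and the flip is recorded on the
  estimate. The operation is an involution; applying it twice is the
  identity.

No outlier handling is performed at any point; what goes into
`standardize()` is what the study recorded.

## Posterior sampling

Both regressions are Bayesian with non-informative priors. Two samplers
are provided:

* **`prior = "flat"` (default):** improper uniform priors on coefficients
  and $p(\sigma^2) \propto 1/\sigma^2$. The posterior then factorises into
  two normal–inverse-gamma blocks with known closed form, so the sampler
  draws *exact independent* samples:
  $\sigma^2 \mid y \sim \text{RSS}/\chi^2_{n-p}$, then
  $\beta \mid \sigma^2 \sim N(\hat\beta, \sigma^2 (X'X)^{-1})$. Posterior
  coefficient means equal the least-squares estimates up to Monte-Carlo
  error — the invariant the test suite checks against a normal-equations
  oracle.
* **`prior = "weak_normal"`:** $N(0, 100^2)$ coefficients and
  inverse-gamma(0.001, 0.001) variances, sampled by Gibbs. This is the
  standard weakly-informative alternative; results are insensitive to the
  choice for any data with real variation.

The default configuration runs 3 chains of 20,000 draws. The historical
large-scale protocol for this kind of analysis — 3 chains of $10^6$
iterations, burn-in 5,000, thinning 10 — is available through
`mediation_config()`, but with exact independent draws burn-in and
thinning are no-ops and $10^6$ iterations buy nothing; they are honoured
in the retained-draw accounting (`n_chains * (n_iter - burn_in) / thin`)
and genuinely matter only under the Gibbs path.

Convergence is monitored with the classic Gelman–Rubin statistic
$\hat R = \sqrt{((n-1)W/n + B/n)/W}$ (not the split/rank variant), with
the usual $\le 1.01$ bar. Any larger $\hat R$ sets a warning flag on the
posterior rather than aborting, since a flagged estimate is still
inspectable. Note $\hat R$ can fall slightly below 1 (its floor is
$\sqrt{(n-1)/n}$) when chains agree closely.

Derived quantities are computed draw-by-draw: indirect draws are the
elementwise product $\beta_1^{(s)} \beta_3^{(s)}$, total draws the
elementwise sum with $\beta_4^{(s)}$, so all reported intervals propagate
the joint uncertainty. Summaries are the draw mean, SD, and equal-tailed
95% interval from the 2.5/97.5 empirical percentiles; at least 100
retained draws are required before percentile summaries are reported.

## Per-study estimates and pooling

For meta-analysis each study contributes its posterior mean $y_i$ and the
variance of its retained draws $v_i$ — the natural draw-based variance
definition, since the pooling step is frequentist and needs a sampling
variance for the Bayesian point estimate. When a study yields several
estimates of one family (several outcomes or markers),
`select_most_precise()` keeps the minimum-$v$ estimate, breaking ties by
the study's declared primary-outcome order and then lexically — a
deterministic rule, recorded in the report so the selection is auditable.

The two effect families are pooled in *independent* random-effects
meta-analyses:

* **Between-study variance** $\tau^2$ by the empirical-Bayes /
  Paule–Mandel estimating equation
  $\sum_i w_i(\tau^2) (y_i - \hat\mu(\tau^2))^2 = k - 1$ with
  $w_i = 1/(v_i + \tau^2)$, solved by Newton iteration to
  $|\Delta\tau^2| < 10^{-8}$ (max 100 iterations) and truncated at zero.
  The dispersion function is decreasing and convex in $\tau^2$, so Newton
  from $\tau^2 = 0$ converges monotonically whenever a positive root
  exists. The reported SE of $\tau^2$ uses the large-sample
  profile-information form $\sqrt{2/\sum w_i^2}$; other software uses
  related but not identical variance formulas, so small discrepancies in
  this SE (only) are expected.
* **Heterogeneity**: Cochran's $Q = \sum (y_i - \hat\mu_{FE})^2 / v_i$
  against $\chi^2_{k-1}$.
* **Pooled effect**: inverse-variance weighted mean with
  $w_i = 1/(v_i + \tau^2)$, normal-theory 95% CI and two-sided p-value —
  no Knapp–Hartung small-sample adjustment, matching the convention of
  the standard meta-analytic software this mirrors (verified against
  `metafor`'s EB estimator in the test suite).

With a single study there is nothing to pool; `meta_analysis()` then
returns the study's own estimate with $\tau^2 = 0$, $Q = 0$, df 0.

## Within-group association and the ecological trap

The individual-level question — do animals with more new neurons perform
better? — is answered by the ANCOVA slope of $Y$ on $M$ adjusting for
group (`within_group_association()`), not by a regression through all
animals ignoring groups. Two clusters offset on both axes produce a
strong pooled slope with zero within-group association; `ecological_gap()`
flags exactly this pattern (pooled significant, within not). The package
computes both so the contrast is always visible.

## The synthetic-data generator

`generate_study()` draws animal-level data from the same graph the model
fits, on a raw (unstandardised) scale so the pipeline's own
transformations are exercised: $M = \mu_M + b_1 T + N(0, \sigma_M)$,
$Y = \mu_Y + b_3 (M - \mu_M) + b_4 T + N(0, \sigma_Y)$, optionally mapped
through the inverse logit into (0, 100) for percent-bounded outcomes.
Defaults emulate the multi-study animal literature this package targets:
11 studies of 10 animals per arm (220 animals — the scale of a pooled
reanalysis of published neurogenesis experiments), and raw effects
$b_1 = 1$, $b_3 = 0.19$, $b_4 = 1.36$, $\sigma_M = \sigma_Y = 1$. Those
values were chosen analytically, once, from the variance identities

$$\mathrm{Var}(M) = b_1^2 p(1-p) + \sigma_M^2, \qquad
  \mathrm{Var}(Y) = b_3^2 \mathrm{Var}(M) + b_4^2 p(1-p) +
  2 b_1 b_3 b_4 p(1-p) + \sigma_Y^2,$$

so that the population standardised indirect effect
$b_1 b_3/\mathrm{sd}(Y) = 0.149$ and direct effect
$b_4/\mathrm{sd}(Y) = 1.063$ — a small mediated contribution (about 12%
of the total) next to a dominant direct one, with no between-study
heterogeneity ($\tau^2 = 0$). `true_standardized_effects()` exposes this
mapping, and it is the truth against which interval coverage is judged.

Ensembles derive child study seeds as `ensemble_seed * 1000 + i`, so one
integer reproduces every dataset. With `tau2_between > 0`, study-specific
true indirect effects are spread by perturbing $b_3$ (first-order in the
standardised scale), keeping treatment strength and noise common.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: litter effects and other clustering,
measurement error from digitising scatterplots, selective reporting and
publication bias, non-normal behavioural outcomes beyond the logit case,
and multi-arm designs (rejected explicitly by `prepare_study()`).

## Problem sizes and calibration checks

The test suite verifies, at sizes chosen to keep the default run fast on
one CPU while leaving Monte-Carlo error well below the tolerances:

* oracle equivalence of posterior means with least squares on 50 seeded
  studies (judged family-wise at the 3 MC-SE scale, since with exact
  independent draws the comparison statistic is standard normal and 150
  comparisons are made);
* 95% credible-interval coverage for the indirect effect within [92%, 98%]
  and absolute mean bias below 0.03 over 500 studies of 20 animals per
  arm;
* a pooled indirect effect within 2 pooled-SE of zero over 12 studies
  generated with $b_3 = 0$;
* Q-test type-I rate within [3.5%, 6.5%] over 2,000 homogeneous ensembles;
* Paule–Mandel $\tau^2$ within $10^{-3}$ of a grid-search oracle
  (step $10^{-4}$) on 50 random ensembles, and against `metafor`;
* the hand-computable cases $\hat R = \sqrt{1.05} \approx 1.0247$ for
  chains $\{1,2,3,4\}, \{2,3,4,5\}$ and $Q = 2$, $p = 0.157$ for
  $y = \{0, 2\}$, $v = \{1, 1\}$.

`scripts/acceptance.R` re-runs the full pipeline on a fresh ensemble and
reports the pooled estimates, heterogeneity statistics, percent mediated,
and the calibration rates, all seeded from one command-line integer.

## Known limitations

Only two-group studies are supported; multi-arm designs need a different
pooling rule and are rejected loudly. The mediation decomposition is
linear; threshold or saturating mediator effects would be mis-split. The
draw-variance $v_i$ treats the posterior mean as if it were a frequentist
estimate with known variance, which is the standard pragmatic bridge in
this two-stage design but understates uncertainty for very small studies.
Inverse-variance weighting of product-of-coefficient estimates can weight
small-|effect| studies slightly more (their product posteriors are
tighter), which pulls pooled indirect effects toward zero by a small
amount at these sample sizes; the end-to-end recovery test bounds this
within pooled-SE tolerances rather than pretending it away.
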