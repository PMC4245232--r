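# mediameta

How much of an experimental effect on behaviour actually travels through
the biological mediator you measured? Animal studies routinely show that
an intervention changes both hippocampal neurogenesis and behaviour, then
conclude the first caused the second — ignoring everything else the
intervention did. `mediameta` implements the analysis that makes that
inference testable: a Bayesian causal mediation model per study, followed
by random-effects meta-analytic pooling of the standardised estimates
across studies. It is aimed at researchers reanalysing published
animal-level data (cell counts vs task scores) and at methodologists
studying the calibration of this two-stage design.

## The model

For each two-group study with treatment indicator *T*, standardised
mediator *M* and standardised outcome *Y*:

    M = α_M + β₁·T + ε_M
    Y = α_Y + β₃·M + β₄·T + ε_Y

- **indirect effect** = β₁·β₃ — the treatment effect transmitted by the
  mediator (product of coefficients, computed draw-by-draw from the joint
  posterior);
- **direct effect** = β₄ — all other mechanisms;
- **total effect** = β₁·β₃ + β₄.

Both regressions are fit with non-informative priors (exact conjugate
sampling by default; a Gibbs sampler for a weak-normal prior), with
Gelman–Rubin convergence checks. Per-study estimates (posterior mean,
draw variance) are pooled per effect family with a random-effects
meta-analysis: empirical-Bayes (Paule–Mandel) τ², Cochran's Q
heterogeneity test, normal-theory CI and p-value. Percent-bounded
outcomes are logit-transformed, lower-is-better outcomes are sign-flipped
at the estimate level, and studies contributing several estimates are
de-duplicated to their most precise one. A within-group ANCOVA
(`within_group_association()`) gives the valid individual-level
mediator–behaviour test and flags the ecological-fallacy pattern where
only the groups-ignored association is significant.

## Worked example

```r
library(mediameta)

ds   <- generate_study(synthetic_study_spec(n_control = 12L, n_treated = 12L,
                                            seed = 42L), study_id = "demo")
std  <- prepare_study(ds)                       # standardise, encode T
post <- fit_mediation(std, mediation_config(seed = 1L))
print(post)
#> Bayesian mediation posterior (study demo)
#>   60000 retained draws, 3 chain(s),  converged
#>  quantity    mean    sd     q2.5     q50 q97.5
#>    direct  0.8808 0.401  0.08840  0.8793 1.677
#>  indirect -0.0509 0.135 -0.37458 -0.0252 0.186
#>     total  0.8298 0.418  0.00477  0.8274 1.665
```

The treatment improved behaviour by ~0.83 standard deviations in total,
but essentially none of that is attributable to the mediator: the
indirect effect is −0.05 z-units with a 95% credible interval spanning
zero, while other mechanisms account for 0.88 z-units.

The `analysis/` directory chains this per-study fit into the full
multi-study workflow (simulate → fit → pool → report):

```sh
Rscript analysis/01_simulate.R   # 11 two-group studies, 220 animals
Rscript analysis/02_fit.R        # per-study mediation posteriors
Rscript analysis/03_meta.R       # two random-effects meta-analyses
Rscript analysis/04_report.R     # forest table, JSON report, diagnostics
```

which ends with (tables under `results/`):

```
Mediated (indirect) effect:
Random-effects pooled estimate (k = 11 studies)
  0.158  [95% CI 0.027, 0.289]  p = 0.0184
  tau2 = 0 (SE 0.0194); Q(10) = 5.507, p = 0.855

Other mechanisms (direct) effect:
Random-effects pooled estimate (k = 11 studies)
  1.103  [95% CI 0.877, 1.328]  p = 1.07e-21
  tau2 = 0 (SE 0.0564); Q(10) = 7.163, p = 0.710

Mediator contribution to the pooled total effect: 12.5%
```

i.e. across 11 simulated studies generated with a true standardised
indirect effect of 0.149 and direct effect of 1.063, the pipeline
recovers a small mediated contribution (~12% of the total), a dominant
direct effect, and no between-study heterogeneity (τ² = 0) — the
statistical structure these reanalyses exhibit.

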