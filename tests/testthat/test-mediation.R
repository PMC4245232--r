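test_that("flat-prior posterior means match the least-squares oracle", {
  ds <- make_seeded_study(21, n = 25L)
  std <- prepare_study(ds)
  post <- fit_mediation(std, fast_config(seed = 5, n_iter = 4000L))

  Xm <- cbind(1, std$T)
  Xy <- cbind(1, std$M, std$T)
  ls_m <- ls_oracle(Xm, std$M)
  ls_y <- ls_oracle(Xy, std$Y)

  ndraw <- nrow(post$draws)
  for (chk in list(list("beta1", ls_m[2]), list("beta3", ls_y[2]),
                   list("beta4", ls_y[3]))) {
    d <- post$draws[[chk[[1]]]]
    mcse <- sd(d) / sqrt(ndraw)
    expect_lt(abs(mean(d) - chk[[2]]), 3 * mcse + 1e-12)
  }
})

test_that("a null mediator-outcome path yields a null indirect effect", {
  spec <- synthetic_study_spec(n_control = 50000L, n_treated = 50000L,
                               b3 = 0, seed = 9)
  std <- prepare_study(generate_study(spec))
  post <- fit_mediation(std, fast_config(seed = 2))
  expect_lt(abs(mean(post$draws$indirect)), 0.02)
})

test_that("draw accounting follows chains, burn-in and thinning", {
  ds <- make_seeded_study(3)
  std <- prepare_study(ds)
  cfg <- mediation_config(n_chains = 2L, n_iter = 1200L, burn_in = 200L,
                          thin = 2L, seed = 1)
  post <- fit_mediation(std, cfg)
  expect_equal(nrow(post$draws), 2L * (1200L - 200L) %/% 2L)
  expect_equal(sort(unique(post$draws$chain)), c(1L, 2L))
  # derived draws: product and sum identities hold exactly
  expect_identical(post$draws$indirect, post$draws$beta1 * post$draws$beta3)
  expect_identical(post$draws$total, post$draws$beta4 + post$draws$indirect)
  # classic PSRF is bounded below by sqrt((n-1)/n) for agreeing chains
  n_per_chain <- nrow(post$draws) / 2L
  expect_true(all(post$rhat >= sqrt((n_per_chain - 1) / n_per_chain) |
                    is.na(post$rhat)))
})

test_that("the Gibbs path (weak normal prior) agrees with least squares", {
  ds <- make_seeded_study(13, n = 30L)
  std <- prepare_study(ds)
  cfg <- mediation_config(n_chains = 2L, n_iter = 3000L, burn_in = 500L,
                          thin = 1L, seed = 8, prior = "weak_normal")
  post <- fit_mediation(std, cfg)
  expect_equal(nrow(post$draws), 2L * 2500L)
  Xy <- cbind(1, std$M, std$T)
  ls_y <- ls_oracle(Xy, std$Y)
  # wide prior: posterior mean within a few posterior SDs scaled by MC error
  expect_lt(abs(mean(post$draws$beta3) - ls_y[2]),
            5 * sd(post$draws$beta3) / sqrt(nrow(post$draws) / 10))
  expect_true(all(post$rhat[c("beta1", "beta3", "beta4")] < 1.05))
})

test_that("a mediator collinear with treatment is a degenerate design", {
  meta <- study_meta("col", control_group = "control")
  rec <- data.frame(
    animal_id = paste0("a", 1:8),
    group = rep(c("control", "treated"), each = 4),
    mediator = rep(c(1, 2), each = 4),  # varies only between groups
    outcome = c(0.1, -0.2, 0.3, 0, 1.1, 0.8, 1.2, 0.9))
  ds <- study_dataset(meta, rec)
  std <- prepare_study(ds)
  expect_error(fit_mediation(std, fast_config()), "degenerate-design")
})

test_that("indirect draws are the elementwise product of the two paths", {
  expect_equal(indirect_draws(c(1, 2), c(3, 4)), c(3, 8))
  expect_equal(indirect_draws(c(0, 0), c(3, 4)), c(0, 0))
  expect_equal(indirect_draws(c(1, -1), c(2, 2)), c(2, -2))
  expect_error(indirect_draws(c(1, 2), c(3, 4, 5)),
               "internal-consistency")
  post <- fit_mediation(prepare_study(make_seeded_study(2)), fast_config())
  expect_identical(indirect_draws(post), post$draws$indirect)
})

test_that("summarize_effect gives equal-tailed intervals from percentiles", {
  s <- summarize_effect(rep(1, 200))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  expect_equal(c(s$q2.5, s$q97.5), c(1, 1))

  withr::local_seed(6)
  z <- rnorm(1e6)
  s <- summarize_effect(z)
  expect_equal(s$q2.5, -1.96, tolerance = 0.01)
  expect_equal(s$q97.5, 1.96, tolerance = 0.01)
  expect_equal(s$q50, 0, tolerance = 0.01)

  expect_error(summarize_effect(rnorm(10)), "precision error")
})

test_that("percent mediated reproduces the headline contribution ratios", {
  expect_equal(percent_mediated(0.15, 1.06), 100 * 0.15 / 1.21)
  expect_equal(percent_mediated(0.15, 1.06), 12.4, tolerance = 0.01)
  expect_equal(percent_mediated(0.399, 0.623), 39.0, tolerance = 0.05)
  expect_equal(percent_mediated(0, 1), 0)
  expect_warning(percent_mediated(-0.2, 0.5), "suppression")
  expect_error(percent_mediated(0.3, -0.3), "undefined-proportion")
})

test_that("Gelman-Rubin matches the hand-computed PSRF and its limits", {
  # W = 5/3, B = 2, n = 4 -> sqrt(((3/4)(5/3) + 1/2)/(5/3)) = sqrt(1.05)
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(2, 3, 4, 5))),
               sqrt(1.05))
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(2, 3, 4, 5))), 1.0247,
               tolerance = 1e-4)

  withr::local_seed(12)
  x <- rnorm(5000)
  expect_lte(gelman_rubin(list(x, x)), 1)

  expect_error(gelman_rubin(list(1:10)), "undefined-diagnostic")
  expect_error(gelman_rubin(list(rep(1, 5), rep(1, 5))), "degenerate")
})

test_that("well-mixed chains on clean synthetic data pass the 1.01 bar", {
  post <- fit_mediation(prepare_study(make_seeded_study(17, n = 15L)),
                        fast_config(seed = 3))
  expect_true(all(post$rhat <= 1.01))
  expect_true(post$converged)
})

test_that("orientation flips effect draws at the estimate level only", {
  std <- prepare_study(make_seeded_study(5))
  post <- fit_mediation(std, fast_config(seed = 4))

  same <- orient_effects(post, "higher_is_better")
  expect_identical(same$draws, post$draws)

  flip <- orient_effects(post, "lower_is_better")
  expect_equal(flip$draws$indirect, -post$draws$indirect)
  expect_equal(flip$draws$beta4, -post$draws$beta4)
  expect_equal(flip$draws$total, -post$draws$total)
  # mediator-model paths untouched; only the estimate signs move
  expect_identical(flip$draws$beta1, post$draws$beta1)
  expect_true(flip$sign_flipped)
  s_ind <- function(p) p$summaries[p$summaries$quantity == "indirect", ]
  expect_equal(s_ind(flip)$mean, -s_ind(post)$mean)
  expect_equal(s_ind(flip)$q2.5, -s_ind(post)$q97.5)

  # involution restores the original
  back <- orient_effects(flip, "lower_is_better")
  expect_equal(back$draws, post$draws)
  expect_false(back$sign_flipped)
})

test_that("effect estimates carry posterior mean, draw variance and CI", {
  post <- fit_mediation(prepare_study(make_seeded_study(6)),
                        fast_config(seed = 6))
  est <- effect_estimate(post, "indirect")
  expect_equal(est$y, mean(post$draws$indirect))
  expect_equal(est$v, var(post$draws$indirect))
  expect_true(est$v > 0)
  expect_true(est$ci_low <= est$y && est$y <= est$ci_high)
  est_d <- effect_estimate(post, "direct")
  expect_equal(est_d$y, mean(post$draws$beta4))
})
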