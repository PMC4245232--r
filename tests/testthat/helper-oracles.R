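# Independent oracles and small fixture builders shared across tests.

# Least squares via the normal equations (deliberately not qr/lm, which the
# implementation uses internally).
ls_oracle <- function(X, y) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# Coefficient, SE and two-sided t-test p-value for one column of a
# least-squares fit, from the normal equations.
ls_ttest_oracle <- function(X, y, col) {
  XtX_inv <- solve(crossprod(X))
  b <- drop(XtX_inv %*% crossprod(X, y))
  resid <- y - drop(X %*% b)
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * diag(XtX_inv))
  t <- b / se
  list(estimate = unname(b[col]), se = unname(se[col]),
       p = unname(2 * stats::pt(abs(t[col]), df, lower.tail = FALSE)))
}

# Grid-search oracle for the Paule-Mandel estimating equation
# sum(w (y - mu)^2) = k - 1 over tau2 in [0, hi].
grid_tau2_oracle <- function(y, v, hi = 10, step = 1e-4) {
  k <- length(y)
  grid <- seq(0, hi, by = step)
  disc <- vapply(grid, function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2) - (k - 1)
  }, numeric(1))
  if (disc[1] <= 0) return(0)
  grid[which.min(abs(disc))]
}

# Minimal two-group study dataset from explicit vectors.
make_study <- function(mediator, outcome, group,
                       control = "control",
                       orientation = "higher_is_better",
                       scale = "linear",
                       study_id = "toy") {
  meta <- study_meta(study_id = study_id, control_group = control,
                     outcome_orientation = orientation,
                     outcome_scale = scale)
  study_dataset(meta, data.frame(
    animal_id = sprintf("a%02d", seq_along(mediator)),
    group = group, mediator = mediator, outcome = outcome))
}

# A quick seeded two-group study with signal on both paths.
make_seeded_study <- function(seed, n = 10L, b1 = 1, b3 = 0.19, b4 = 1.36) {
  generate_study(synthetic_study_spec(
    n_control = n, n_treated = n, b1 = b1, b3 = b3, b4 = b4, seed = seed))
}

# Fast sampler settings for tests: 3 chains x 1500 independent draws.
fast_config <- function(seed = 1L, n_iter = 1500L, ...) {
  mediation_config(n_chains = 3L, n_iter = n_iter, seed = seed, ...)
}

write_toy_csv <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      animal_id = paste0("a", 1:6),
      group = rep(c("control", "treated"), each = 3),
      mediator = c(10, 12, 11, 15, 16, 14),
      outcome = c(1.0, 1.2, 0.9, 2.1, 2.3, 2.0))
  }
  utils::write.csv(rows, path, row.names = FALSE)
  path
}
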