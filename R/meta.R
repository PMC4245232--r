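#' Keep the most precise estimate per study
#'
#' Studies often contribute several estimates of the same quantity (several
#' behavioural outcomes, several mediator markers). To avoid double
#' counting, only the estimate with the smallest posterior variance `v` is
#' carried into the combined analysis. Ties are broken deterministically:
#' first by the study's declared primary-outcome order (the
#' `primary_outcomes` field of [study_meta()], passed here as
#' `outcome_order`), then by lexical order of the outcome label.
#'
#' @param estimates Data frame of effect estimates (rows as produced by
#'   [effect_estimate()]), possibly several per study.
#' @param outcome_order Optional character vector; outcome labels earlier
#'   in this vector win ties.
#' @return Data frame with one row per `study_id`, in first-appearance
#'   study order.
#' @export
select_most_precise <- function(estimates, outcome_order = character()) {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    stop("empty-input error: no estimates to select from", call. = FALSE)
  }
  stopifnot(all(c("study_id", "y", "v") %in% names(estimates)))
  rank_of <- function(label) {
    r <- match(label, outcome_order)
    ifelse(is.na(r), length(outcome_order) + 1L, r)
  }
  pick <- function(rows) {
    sub <- estimates[rows, , drop = FALSE]
    best <- which(sub$v == min(sub$v))
    if (length(best) > 1L) {
      lab <- as.character(sub$outcome_label[best])
      lab[is.na(lab)] <- ""
      best <- best[order(rank_of(lab), lab)]
    }
    rows[best[1L]]
  }
  ids <- unique(estimates$study_id)
  keep <- vapply(ids, function(id) pick(which(estimates$study_id == id)),
                 integer(1L))
  out <- estimates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Inverse-variance weighted mean at a given tau2.
weighted_mu <- function(y, v, tau2) {
  w <- 1 / (v + tau2)
  sum(w * y) / sum(w)
}

#' Empirical-Bayes (Paule-Mandel) between-study variance
#'
#' Solves the Paule-Mandel estimating equation
#' \deqn{\sum_i w_i(\tau^2)\,(y_i - \hat\mu(\tau^2))^2 = k - 1,
#'       \quad w_i = 1/(v_i + \tau^2),}
#' by iteration to `|delta tau2| < tol`, truncating at zero when the
#' observed dispersion is smaller than expected under homogeneity. The
#' standard error is the large-sample information-based form
#' `sqrt(2 / sum(w_i^2))` evaluated at the solution.
#'
#' @param y Study point estimates (standardised z-units).
#' @param v Their sampling variances (all > 0), length matching `y`.
#' @param tol Convergence tolerance on tau2. Default 1e-8.
#' @param max_iter Maximum iterations. Default 100.
#' @return List: `tau2`, `tau2_se`, `iterations`, `converged`.
#' @export
eb_tau2 <- function(y, v, tol = 1e-8, max_iter = 100L) {
  k <- length(y)
  stopifnot(k >= 2L, length(v) == k, all(v > 0))
  disc <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2) - (k - 1)
  }
  tau2 <- 0
  converged <- FALSE
  iterations <- 0L
  if (disc(0) <= 0) {
    # observed dispersion below sampling expectation: truncate at 0
    converged <- TRUE
  } else {
    # Newton iteration on the estimating equation; the derivative of the
    # generalised Q in tau2 is -sum(w^2 (y - mu)^2) (mu-derivative term
    # vanishes at the weighted mean).
    for (iterations in seq_len(max_iter)) {
      w <- 1 / (v + tau2)
      mu <- sum(w * y) / sum(w)
      q_gen <- sum(w * (y - mu)^2)
      deriv <- -sum(w^2 * (y - mu)^2)
      tau2_new <- tau2 - (q_gen - (k - 1)) / deriv
      if (tau2_new < 0) tau2_new <- 0
      if (abs(tau2_new - tau2) < tol) {
        tau2 <- tau2_new
        converged <- TRUE
        break
      }
      tau2 <- tau2_new
    }
    if (!converged) {
      stop("convergence error: Paule-Mandel iteration did not converge ",
           "after ", max_iter, " iterations; last tau2 = ",
           format(tau2, digits = 10), call. = FALSE)
    }
  }
  w <- 1 / (v + tau2)
  list(tau2 = tau2, tau2_se = sqrt(2 / sum(w^2)),
       iterations = iterations, converged = converged)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum((1/v_i) * (y_i - mu_FE)^2)` with `mu_FE` the fixed-effect
#' (inverse-variance weighted) mean, referred to a chi-square distribution
#' with k - 1 degrees of freedom.
#'
#' @inheritParams eb_tau2
#' @return List: `Q`, `df`, `p_Q`.
#' @export
q_statistic <- function(y, v) {
  k <- length(y)
  stopifnot(k >= 2L, length(v) == k, all(v > 0))
  mu_fe <- weighted_mu(y, v, 0)
  Q <- sum((y - mu_fe)^2 / v)
  df <- k - 1L
  list(Q = Q, df = df, p_Q = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Random-effects pooled estimate
#'
#' Inverse-variance pooling with weights `w_i = 1/(v_i + tau2)`:
#' pooled mean, its standard error `sqrt(1/sum(w))`, normal (z) 95%
#' confidence limits and two-sided p-value. No small-sample (Knapp-Hartung)
#' adjustment is applied.
#'
#' @inheritParams eb_tau2
#' @param tau2 Between-study variance (>= 0), typically from [eb_tau2()].
#' @return List: `pooled`, `se`, `ci_low`, `ci_high`, `p`, `k`, `weights`.
#' @export
pool_random_effects <- function(y, v, tau2 = 0) {
  k <- length(y)
  stopifnot(k >= 2L, length(v) == k, all(v > 0), tau2 >= 0)
  w <- 1 / (v + tau2)
  pooled <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(0.975)
  list(pooled = pooled, se = se,
       ci_low = pooled - z * se, ci_high = pooled + z * se,
       p = 2 * stats::pnorm(abs(pooled) / se, lower.tail = FALSE),
       k = k, weights = w)
}

#' Full random-effects meta-analysis of one effect family
#'
#' Convenience wrapper: estimates tau2 by [eb_tau2()], tests heterogeneity
#' with [q_statistic()], and pools with [pool_random_effects()].
#'
#' @param estimates Data frame with columns `y` and `v` (one row per
#'   study; run [select_most_precise()] first when studies contribute
#'   multiple estimates).
#' @return Object of class `meta_result` with fields `pooled`, `se`,
#'   `ci_low`, `ci_high`, `p`, `tau2`, `tau2_se`, `Q`, `df`, `p_Q`, `k`.
#' @export
meta_analysis <- function(estimates) {
  stopifnot(all(c("y", "v") %in% names(estimates)))
  y <- estimates$y; v <- estimates$v
  if (length(y) == 1L) {
    # a single study: nothing to pool or test heterogeneity over
    return(structure(
      list(pooled = y, se = sqrt(v),
           ci_low = y - stats::qnorm(0.975) * sqrt(v),
           ci_high = y + stats::qnorm(0.975) * sqrt(v),
           p = 2 * stats::pnorm(abs(y) / sqrt(v), lower.tail = FALSE),
           tau2 = 0, tau2_se = NA_real_, Q = 0, df = 0L, p_Q = NA_real_,
           k = 1L),
      class = "meta_result"))
  }
  tau <- eb_tau2(y, v)
  qq <- q_statistic(y, v)
  pool <- pool_random_effects(y, v, tau$tau2)
  structure(
    list(pooled = pool$pooled, se = pool$se, ci_low = pool$ci_low,
         ci_high = pool$ci_high, p = pool$p,
         tau2 = tau$tau2, tau2_se = tau$tau2_se,
         Q = qq$Q, df = qq$df, p_Q = qq$p_Q, k = pool$k),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects pooled estimate (k = %d studies)\n", x$k))
  cat(sprintf("  %.3f  [95%% CI %.3f, %.3f]  p = %.3g\n",
              x$pooled, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  tau2 = %.4g (SE %.3g); Q(%d) = %.3f, p = %.3f\n",
              x$tau2, x$tau2_se, x$df, x$Q, x$p_Q))
  invisible(x)
}

#' Serialise meta-analysis inputs or results
#'
#' `write_estimates_csv()` writes the per-study estimate table
#' (`study_id, quantity, y, v, ci_low, ci_high`); `meta_result_json()`
#' renders a `meta_result` as a JSON string at full precision.
#'
#' @param estimates Data frame of effect estimates.
#' @param path Output CSV path.
#' @return `write_estimates_csv()`: the path, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  cols <- intersect(
    c("study_id", "quantity", "outcome_label", "y", "v", "ci_low",
      "ci_high", "sign_flipped"),
    names(estimates))
  utils::write.csv(estimates[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_csv
#' @param result A `meta_result`.
#' @export
meta_result_json <- function(result) {
  stopifnot(inherits(result, "meta_result"))
  jsonlite::toJSON(unclass(result), auto_unbox = TRUE, digits = NA)
}
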