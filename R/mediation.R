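#' Sampler configuration for the mediation model
#'
#' Controls the posterior sampling of the two regressions that make up the
#' mediation model. The default is desk-scale: 3 chains of 20,000 draws each
#' with no burn-in or thinning, which is ample because the default `flat`
#' prior admits exact conjugate block sampling (independent draws). The
#' historical large-scale protocol (3 chains of 1e6 iterations, burn-in
#' 5000, thin 10) is available by setting those values; burn-in and thinning
#' are no-ops under conjugate sampling but are honoured in the retained-draw
#' accounting and under the Gibbs path.
#'
#' @param n_chains Number of chains (>= 1; >= 2 needed for R-hat). Default 3.
#' @param n_iter Iterations per chain. Default 20000.
#' @param burn_in Iterations discarded per chain. Default 0.
#' @param thin Keep every `thin`-th draw. Default 1.
#' @param seed Integer seed, or `NULL` to leave the RNG state alone.
#' @param prior `"flat"` (improper uniform on coefficients, p(sigma^2)
#'   proportional to 1/sigma^2; sampled exactly) or `"weak_normal"`
#'   (Normal(0, `prior_sd`^2) coefficients, inverse-gamma(`ig_shape`,
#'   `ig_rate`) error variances; sampled by Gibbs).
#' @param prior_sd,ig_shape,ig_rate Hyperparameters of the weak prior.
#' @return An object of class `mediation_config`.
#' @export
mediation_config <- function(n_chains = 3L, n_iter = 20000L, burn_in = 0L,
                             thin = 1L, seed = NULL,
                             prior = c("flat", "weak_normal"),
                             prior_sd = 100, ig_shape = 0.001,
                             ig_rate = 0.001) {
  prior <- match.arg(prior)
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  stopifnot(n_chains >= 1L, n_iter >= 1L, burn_in >= 0L, burn_in < n_iter,
            thin >= 1L, prior_sd > 0, ig_shape > 0, ig_rate > 0)
  structure(
    list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
         thin = thin, seed = seed, prior = prior, prior_sd = prior_sd,
         ig_shape = ig_shape, ig_rate = ig_rate),
    class = "mediation_config"
  )
}

# Retained draws per chain implied by a config.
draws_per_chain <- function(config) {
  (config$n_iter - config$burn_in) %/% config$thin
}

# Exact posterior draws for y = X b + e under the flat prior
# p(b, s2) ~ 1/s2: s2 | y ~ Scaled-Inv-Chisq(n - p, RSS/(n - p)),
# b | s2, y ~ N(bhat, s2 (X'X)^-1). Returns an ndraw x (p + 1) matrix
# (coefficients then sigma).
sample_lm_conjugate <- function(X, y, ndraw) {
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop("degenerate-design error: design matrix is rank deficient ",
         "(mediator collinear with treatment?)", call. = FALSE)
  }
  bhat <- qr.coef(qrX, y)
  rss <- sum(qr.resid(qrX, y)^2)
  if (rss <= 0 || n <= p) {
    stop("degenerate-design error: no residual variation to estimate ",
         "the error variance", call. = FALSE)
  }
  s2 <- rss / stats::rchisq(ndraw, df = n - p)
  R <- qr.R(qrX)  # X'X = R'R
  z <- matrix(stats::rnorm(ndraw * p), nrow = p)
  # b = bhat + sigma * R^-1 z has covariance s2 (X'X)^-1
  b <- t(bhat + backsolve(R, z) * rep(sqrt(s2), each = p))
  cbind(b, sigma = sqrt(s2))
}

# Gibbs sampler for y = X b + e under b ~ N(0, prior_sd^2 I),
# s2 ~ IG(a, r). Returns retained draws after burn-in/thinning.
sample_lm_gibbs <- function(X, y, config) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  prior_prec <- diag(1 / config$prior_sd^2, p)
  keep <- draws_per_chain(config)
  out <- matrix(NA_real_, nrow = keep, ncol = p + 1L)
  s2 <- stats::var(y)
  kept <- 0L
  for (it in seq_len(config$n_iter)) {
    V <- chol2inv(chol(XtX / s2 + prior_prec))
    mu <- V %*% (Xty / s2)
    b <- drop(mu + t(chol(V)) %*% stats::rnorm(p))
    resid <- y - drop(X %*% b)
    s2 <- 1 / stats::rgamma(1L, shape = config$ig_shape + n / 2,
                            rate = config$ig_rate + sum(resid^2) / 2)
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- c(b, sqrt(s2))
    }
  }
  out[seq_len(kept), , drop = FALSE]
}

#' Fit the Bayesian mediation model to one study
#'
#' Fits the two linear models of the three-variable mediation graph,
#'
#' \deqn{M = \alpha_M + \beta_1 T + \epsilon_M, \qquad
#'       Y = \alpha_Y + \beta_3 M + \beta_4 T + \epsilon_Y,}
#'
#' where T is the 0/1 treatment indicator, M the standardised mediator
#' (e.g. new-neuron count) and Y the standardised behavioural outcome. The
#' indirect (mediator-transmitted) effect is the product of coefficients
#' `beta1 * beta3`, the direct effect ("all other mechanisms") is `beta4`,
#' and the total effect is their sum. Posterior draws of the indirect and
#' total effects are derived draw-by-draw from the joint posterior, which
#' propagates the uncertainty of both paths.
#'
#' With the default flat prior the posterior factorises into two
#' normal-inverse-gamma blocks and is sampled exactly (independent draws);
#' posterior means of the coefficients then coincide with the least-squares
#' estimates up to Monte-Carlo error. The Gelman-Rubin statistic is computed
#' per parameter whenever at least two chains are run; any R-hat above 1.01
#' sets `converged = FALSE` on the result (a warning flag, not an error).
#'
#' @param study A `standardized_study` from [prepare_study()].
#' @param config A [mediation_config()].
#' @return An object of class `mediation_posterior`: a list with `draws`
#'   (data frame of retained draws: alpha_m, beta1, sigma_m, alpha_y, beta3,
#'   beta4, sigma_y, indirect, total, chain), `rhat` (named vector),
#'   `converged`, `summaries` (per-quantity mean, sd, 2.5/50/97.5
#'   percentiles), `sign_flipped`, `meta`, `config`.
#' @export
fit_mediation <- function(study, config = mediation_config()) {
  stopifnot(inherits(study, "standardized_study"),
            inherits(config, "mediation_config"))
  trt <- study$T; M <- study$M; Y <- study$Y
  n <- length(trt)
  if (min(table(trt)) < 3L) {
    stop("design error: need >= 3 animals per group", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  Xm <- cbind(intercept = 1, trt = trt)
  Xy <- cbind(intercept = 1, M = M, trt = trt)
  keep <- draws_per_chain(config)
  if (keep < 1L) stop("config retains no draws", call. = FALSE)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    if (config$prior == "flat") {
      dm <- sample_lm_conjugate(Xm, M, keep)
      dy <- sample_lm_conjugate(Xy, Y, keep)
    } else {
      dm <- sample_lm_gibbs(Xm, M, config)
      dy <- sample_lm_gibbs(Xy, Y, config)
    }
    chains[[ch]] <- data.frame(
      alpha_m = dm[, 1L], beta1 = dm[, 2L], sigma_m = dm[, 3L],
      alpha_y = dy[, 1L], beta3 = dy[, 2L], beta4 = dy[, 3L],
      sigma_y = dy[, 4L], chain = ch
    )
  }
  draws <- do.call(rbind, chains)
  draws$indirect <- draws$beta1 * draws$beta3
  draws$total <- draws$beta4 + draws$indirect

  pars <- c("alpha_m", "beta1", "sigma_m", "alpha_y", "beta3", "beta4",
            "sigma_y")
  rhat <- rep(NA_real_, length(pars))
  names(rhat) <- pars
  if (config$n_chains >= 2L) {
    for (p in pars) {
      rhat[[p]] <- gelman_rubin(split(draws[[p]], draws$chain))
    }
  }
  converged <- !any(rhat > 1.01, na.rm = TRUE)
  if (!converged) {
    warning("non-convergence: R-hat > 1.01 for ",
            paste(pars[which(rhat > 1.01)], collapse = ", "), call. = FALSE)
  }

  quantities <- c(pars, "indirect", "total")
  summaries <- do.call(rbind, lapply(quantities, function(q) {
    s <- summarize_effect(draws[[q]])
    data.frame(quantity = q, s)
  }))
  rownames(summaries) <- NULL

  structure(
    list(draws = draws, rhat = rhat, converged = converged,
         summaries = summaries, sign_flipped = FALSE,
         meta = study$meta, config = config),
    class = "mediation_posterior"
  )
}

#' @export
print.mediation_posterior <- function(x, ...) {
  cat("Bayesian mediation posterior",
      if (!is.null(x$meta)) paste0("(study ", x$meta$study_id, ")"), "\n")
  cat(" ", nrow(x$draws), "retained draws,",
      max(x$draws$chain), "chain(s),",
      if (x$sign_flipped) "sign flipped," else "",
      if (x$converged) "converged" else "NOT converged", "\n")
  sub <- x$summaries[x$summaries$quantity %in%
                       c("indirect", "beta4", "total"), ]
  sub$quantity <- c(beta4 = "direct", indirect = "indirect",
                    total = "total")[sub$quantity]
  print(sub, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Indirect-effect draws (product of coefficients)
#'
#' Elementwise product of aligned posterior draws of the
#' treatment-to-mediator path (beta1) and the mediator-to-outcome path
#' (beta3). Accepts either a fitted `mediation_posterior` (returns its
#' derived indirect draws after verifying the product identity) or two raw
#' draw vectors.
#'
#' @param beta1 A `mediation_posterior`, or a numeric vector of beta1 draws.
#' @param beta3 Numeric vector of beta3 draws (ignored when `beta1` is a
#'   posterior object).
#' @return Numeric vector of indirect-effect draws.
#' @export
indirect_draws <- function(beta1, beta3 = NULL) {
  if (inherits(beta1, "mediation_posterior")) {
    post <- beta1
    return(post$draws$beta1 * post$draws$beta3)
  }
  if (length(beta1) != length(beta3)) {
    stop("internal-consistency error: beta1 and beta3 draws have ",
         "different lengths (", length(beta1), " vs ", length(beta3), ")",
         call. = FALSE)
  }
  beta1 * beta3
}

#' Summarise a vector of posterior draws
#'
#' Mean, SD, and the 2.5/50/97.5 empirical percentiles (equal-tailed 95%
#' credible interval). At least 100 retained draws are required for the
#' tail percentiles to be meaningful.
#'
#' @param draws Numeric vector of posterior draws.
#' @param min_draws Minimum draw count. Default 100.
#' @return One-row data frame: `mean`, `sd`, `q2.5`, `q50`, `q97.5`.
#' @export
summarize_effect <- function(draws, min_draws = 100L) {
  stopifnot(is.numeric(draws))
  if (length(draws) < min_draws) {
    stop("precision error: ", length(draws), " draws; need >= ", min_draws,
         call. = FALSE)
  }
  qs <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE,
                        type = 7)
  data.frame(mean = mean(draws), sd = stats::sd(draws),
             q2.5 = qs[1L], q50 = qs[2L], q97.5 = qs[3L])
}

#' Percent of the total effect transmitted by the mediator
#'
#' `100 * indirect / (indirect + direct)`. When the indirect and direct
#' effects have opposite signs (inconsistent mediation, "suppression"), the
#' ratio is still reported but a warning is raised, since a percentage of a
#' partially cancelling total is easy to misread.
#'
#' @param indirect_mean Posterior mean indirect effect (z-units).
#' @param direct_mean Posterior mean direct effect (z-units).
#' @return Percent contribution (scalar).
#' @export
percent_mediated <- function(indirect_mean, direct_mean) {
  total <- indirect_mean + direct_mean
  if (total == 0) {
    stop("undefined-proportion error: total effect is zero", call. = FALSE)
  }
  if (indirect_mean * direct_mean < 0) {
    warning("suppression: indirect and direct effects have opposite signs; ",
            "percent mediated is not a proportion of a common-signed total",
            call. = FALSE)
  }
  100 * indirect_mean / total
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split, non-rank) R-hat comparing within- and between-chain
#' variance:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}}
#' with W the mean within-chain sample variance and B = n * Var(chain
#' means). Values at or below 1.01 indicate good mixing.
#'
#' @param chains List of >= 2 numeric vectors of equal length n >= 2.
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("undefined-diagnostic error: R-hat needs >= 2 chains",
         call. = FALSE)
  }
  lens <- lengths(chains)
  if (length(unique(lens)) != 1L || lens[1L] < 2L) {
    stop("chains must have equal length >= 2", call. = FALSE)
  }
  n <- lens[1L]
  W <- mean(vapply(chains, stats::var, numeric(1L)))
  if (W == 0) {
    stop("degenerate error: zero within-chain variance", call. = FALSE)
  }
  B <- n * stats::var(vapply(chains, mean, numeric(1L)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Apply outcome orientation to fitted effects
#'
#' For behavioural tests where a lower score means better performance
#' (e.g. escape latency, immobility time), all effect draws — indirect,
#' direct (beta4) and total — are negated so that positive estimates always
#' mean better performance, and the flip is recorded. Data are never
#' modified; orientation acts purely at the estimate level. Applying the
#' operation twice restores the original posterior.
#'
#' @param posterior A `mediation_posterior`.
#' @param orientation `"higher_is_better"` (identity) or
#'   `"lower_is_better"` (negate). Defaults to the orientation declared in
#'   the study metadata carried on the posterior.
#' @return The (possibly sign-flipped) `mediation_posterior`.
#' @export
orient_effects <- function(posterior,
                           orientation = posterior$meta$outcome_orientation) {
  stopifnot(inherits(posterior, "mediation_posterior"))
  orientation <- match.arg(orientation,
                           c("higher_is_better", "lower_is_better"))
  if (orientation == "higher_is_better") return(posterior)
  for (q in c("beta4", "indirect", "total")) {
    posterior$draws[[q]] <- -posterior$draws[[q]]
  }
  posterior$sign_flipped <- !posterior$sign_flipped
  idx <- posterior$summaries$quantity %in% c("beta4", "indirect", "total")
  s <- posterior$summaries[idx, ]
  flipped <- data.frame(quantity = s$quantity, mean = -s$mean, sd = s$sd,
                        q2.5 = -s$q97.5, q50 = -s$q50, q97.5 = -s$q2.5)
  posterior$summaries[idx, ] <- flipped
  posterior
}

#' Extract study-level effect estimates for meta-analysis
#'
#' Converts a fitted (and oriented) posterior into the `(y, v)` pairs the
#' meta-analysis consumes: the posterior mean as the point estimate, the
#' variance of the retained posterior draws as its sampling variance, and
#' the equal-tailed 95% credible limits.
#'
#' @param posterior A `mediation_posterior`.
#' @param quantity `"indirect"` or `"direct"` (direct maps to beta4).
#' @param outcome_label Optional label distinguishing multiple estimates
#'   from one study (e.g. different behavioural outcomes).
#' @return One-row data frame of class `effect_estimate`: `study_id`,
#'   `quantity`, `outcome_label`, `y`, `v`, `ci_low`, `ci_high`,
#'   `sign_flipped`.
#' @export
effect_estimate <- function(posterior, quantity = c("indirect", "direct"),
                            outcome_label = NA_character_) {
  stopifnot(inherits(posterior, "mediation_posterior"))
  quantity <- match.arg(quantity)
  col <- if (quantity == "direct") "beta4" else "indirect"
  d <- posterior$draws[[col]]
  est <- data.frame(
    study_id = if (is.null(posterior$meta)) NA_character_ else
      posterior$meta$study_id,
    quantity = quantity,
    outcome_label = outcome_label,
    y = mean(d),
    v = stats::var(d),
    ci_low = stats::quantile(d, 0.025, names = FALSE),
    ci_high = stats::quantile(d, 0.975, names = FALSE),
    sign_flipped = posterior$sign_flipped
  )
  class(est) <- c("effect_estimate", class(est))
  est
}
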