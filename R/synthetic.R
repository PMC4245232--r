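#' Generative parameters for one simulated animal study
#'
#' Describes a two-group experiment through the same three-variable graph
#' the mediation model fits: treatment shifts the mediator by `b1`
#' (raw units), the mediator carries into the outcome with slope `b3`, and
#' the treatment acts directly on the outcome with `b4`. Defaults emulate
#' the multi-study animal literature the package targets: 10 animals per
#' arm and raw effects chosen so that the *population standardised*
#' indirect effect is about 0.15 and the direct effect about 1.06 (see
#' [true_standardized_effects()] for the mapping).
#'
#' @param n_control,n_treated Animals per arm (>= 3). Default 10 each.
#' @param b1 Treatment-to-mediator effect, in units of `sigma_m`. Default 1.
#' @param b3 Mediator-to-outcome slope. Default 0.19.
#' @param b4 Direct treatment-to-outcome effect. Default 1.36.
#' @param sigma_m,sigma_y Residual SDs (> 0). Default 1.
#' @param mu_m,mu_y Baseline (control-arm) means on the raw scale; the
#'   defaults place cell counts and task scores at plausible assay values
#'   so the pipeline's own standardisation is genuinely exercised.
#' @param outcome_scale `"linear"` or `"percent_bounded"`; for the latter
#'   the linear predictor is treated as a logit and mapped through the
#'   inverse logit into (0, 100).
#' @param orientation Outcome orientation recorded in the study metadata.
#' @param seed Integer seed; identical spec + seed gives identical data.
#' @return Object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_control = 10L, n_treated = 10L,
                                 b1 = 1.0, b3 = 0.19, b4 = 1.36,
                                 sigma_m = 1, sigma_y = 1,
                                 mu_m = 100, mu_y = 0,
                                 outcome_scale = c("linear", "percent_bounded"),
                                 orientation = c("higher_is_better",
                                                 "lower_is_better"),
                                 seed = 1L) {
  outcome_scale <- match.arg(outcome_scale)
  orientation <- match.arg(orientation)
  stopifnot(n_control >= 3L, n_treated >= 3L, sigma_m > 0, sigma_y > 0)
  structure(
    list(n_control = as.integer(n_control), n_treated = as.integer(n_treated),
         b1 = b1, b3 = b3, b4 = b4, sigma_m = sigma_m, sigma_y = sigma_y,
         mu_m = mu_m, mu_y = mu_y, outcome_scale = outcome_scale,
         orientation = orientation, seed = as.integer(seed)),
    class = "synthetic_study_spec"
  )
}

#' Population standardised effects implied by a study spec
#'
#' The pipeline standardises mediator and outcome within each study, so the
#' estimands are the raw effects divided by the population SDs of M and Y.
#' With treatment prevalence `p = n_treated / n`, `Var(T) = p(1-p)` and
#' \deqn{Var(M) = b_1^2 p(1-p) + \sigma_m^2}
#' \deqn{Var(Y) = b_3^2 Var(M) + b_4^2 p(1-p) + 2 b_3 b_4 b_1 p(1-p)
#'       + \sigma_y^2}
#' giving standardised indirect `b1*b3/sd(Y)` and direct `b4/sd(Y)`. These
#' are the true values against which parameter recovery and interval
#' coverage are judged.
#'
#' @param spec A [synthetic_study_spec()].
#' @return List: `indirect`, `direct`, `total`, `sd_m`, `sd_y`.
#' @export
true_standardized_effects <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  n <- spec$n_control + spec$n_treated
  p <- spec$n_treated / n
  var_t <- p * (1 - p)
  var_m <- spec$b1^2 * var_t + spec$sigma_m^2
  var_y <- spec$b3^2 * var_m + spec$b4^2 * var_t +
    2 * spec$b3 * spec$b4 * spec$b1 * var_t + spec$sigma_y^2
  list(indirect = spec$b1 * spec$b3 / sqrt(var_y),
       direct = spec$b4 / sqrt(var_y),
       total = (spec$b1 * spec$b3 + spec$b4) / sqrt(var_y),
       sd_m = sqrt(var_m), sd_y = sqrt(var_y))
}

#' Simulate one animal study
#'
#' Draws animal-level data from the mediation graph on a raw scale:
#' `M = mu_m + b1*T + N(0, sigma_m)`, `Y = mu_y + b3*(M - mu_m) + b4*T +
#' N(0, sigma_y)`; for `percent_bounded` outcomes the linear predictor is
#' mapped through the inverse logit into (0, 100). The mediator enters the
#' outcome model centred at its baseline so `mu_y` stays the control-arm
#' outcome level regardless of `mu_m`.
#'
#' @param spec A [synthetic_study_spec()].
#' @param study_id Study label recorded in the metadata.
#' @return A `study_dataset` (control group `"control"`, treated
#'   `"treated"`).
#' @export
generate_study <- function(spec, study_id = paste0("sim-", spec$seed)) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  set.seed(spec$seed)
  n <- spec$n_control + spec$n_treated
  trt <- rep(c(0L, 1L), c(spec$n_control, spec$n_treated))
  M <- spec$mu_m + spec$b1 * trt + stats::rnorm(n, 0, spec$sigma_m)
  eta <- spec$mu_y + spec$b3 * (M - spec$mu_m) + spec$b4 * trt +
    stats::rnorm(n, 0, spec$sigma_y)
  Y <- if (spec$outcome_scale == "percent_bounded")
    inv_logit_percent(eta) else eta

  meta <- study_meta(
    study_id = study_id,
    control_group = "control",
    outcome_orientation = spec$orientation,
    outcome_scale = spec$outcome_scale,
    species_strain = "synthetic",
    behaviour_test = "synthetic",
    mediator_marker = "synthetic"
  )
  study_dataset(meta, data.frame(
    animal_id = sprintf("a%03d", seq_len(n)),
    group = ifelse(trt == 1L, "treated", "control"),
    mediator = M,
    outcome = Y
  ))
}

#' Generative parameters for a multi-study ensemble
#'
#' @param k Number of studies (>= 2). Default 11, matching the scale of
#'   the animal-study literature the package emulates.
#' @param base A [synthetic_study_spec()] shared by all studies.
#' @param tau2_between Between-study variance of the true *standardised*
#'   indirect effect (>= 0; 0 = homogeneous studies). Default 0.
#' @param seed Ensemble seed; child study seeds are derived as
#'   `seed * 1000 + study index` (documented, deterministic, < 2^31).
#' @return Object of class `synthetic_ensemble_spec`.
#' @export
synthetic_ensemble_spec <- function(k = 11L, base = synthetic_study_spec(),
                                    tau2_between = 0, seed = 1L) {
  stopifnot(k >= 2L, tau2_between >= 0,
            inherits(base, "synthetic_study_spec"))
  structure(
    list(k = as.integer(k), base = base, tau2_between = tau2_between,
         seed = as.integer(seed)),
    class = "synthetic_ensemble_spec"
  )
}

#' Simulate a multi-study ensemble
#'
#' Generates `k` studies from the base spec. With `tau2_between > 0`, each
#' study's true standardised indirect effect is perturbed by
#' `N(0, tau2_between)`; the perturbation is applied to `b3` (rescaled to
#' the raw slope that shifts the standardised indirect by the drawn
#' amount), so treatment-to-mediator strength and noise levels stay common
#' across studies. Child study seeds are `seed * 1000 + i`, so the whole
#' ensemble is reproducible from one integer.
#'
#' @param spec A [synthetic_ensemble_spec()].
#' @return List of `study_dataset`s, named by study id.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ensemble_spec"))
  base <- spec$base
  truth <- true_standardized_effects(base)
  set.seed(spec$seed)
  shift <- if (spec$tau2_between > 0)
    stats::rnorm(spec$k, 0, sqrt(spec$tau2_between)) else numeric(spec$k)
  out <- vector("list", spec$k)
  for (i in seq_len(spec$k)) {
    child <- base
    # move b3 so the standardised indirect shifts by shift[i] (to first
    # order, holding sd_y at the base value)
    child$b3 <- base$b3 + shift[i] * truth$sd_y / base$b1
    child$seed <- spec$seed * 1000L + i
    out[[i]] <- generate_study(child, study_id = sprintf("sim-%02d", i))
  }
  names(out) <- vapply(out, function(s) s$meta$study_id, character(1L))
  out
}
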