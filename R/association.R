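#' Within-group mediator-behaviour association (ANCOVA)
#'
#' The individual-level test of whether animals with more of the mediator
#' (e.g. more new neurons) perform better: the slope of the outcome on the
#' mediator *adjusting for group*, from the least-squares fit
#' `Y ~ T + M` with a common slope across groups. This is contrasted with
#' the pooled slope from `Y ~ M` fit through all animals ignoring groups —
#' the group-level (ecological) association that is so often, and wrongly,
#' quoted as evidence of an individual-level relationship.
#'
#' A group-by-mediator interaction is also screened (fit `Y ~ T * M`): a
#' significant interaction (t-test p < 0.05) means a common-slope ANCOVA
#' misrepresents the data, and a warning flag is set.
#'
#' @param study A `standardized_study` (or any list with numeric `T`, `M`,
#'   `Y` of equal length).
#' @return An object of class `association_result`: `within_slope`,
#'   `within_se`, `within_p`, `pooled_slope`, `pooled_se`, `pooled_p`,
#'   `interaction_p`, `interaction_warning`, `n`.
#' @export
within_group_association <- function(study) {
  trt <- study$T; M <- study$M; Y <- study$Y
  stopifnot(is.numeric(M), is.numeric(Y),
            length(trt) == length(M), length(M) == length(Y))
  grp <- factor(trt)
  if (nlevels(grp) > 1L && min(table(grp)) < 3L) {
    stop("design error: need >= 3 animals per group", call. = FALSE)
  }
  within_sd <- tapply(M, grp, stats::sd)
  if (any(within_sd == 0)) {
    stop("degenerate-covariate error: mediator is constant within a group",
         call. = FALSE)
  }

  # Single-group data degrades gracefully to simple regression of Y on M.
  fit_within <- if (nlevels(grp) > 1L) stats::lm(Y ~ grp + M) else
    stats::lm(Y ~ M)
  cw <- summary(fit_within)$coefficients["M", ]

  fit_pooled <- stats::lm(Y ~ M)
  cp <- summary(fit_pooled)$coefficients["M", ]

  interaction_p <- NA_real_
  if (nlevels(grp) > 1L) {
    fit_int <- stats::lm(Y ~ grp * M)
    ci <- summary(fit_int)$coefficients
    int_rows <- grep(":M$", rownames(ci))
    interaction_p <- min(ci[int_rows, "Pr(>|t|)"])
  }

  structure(
    list(
      within_slope = unname(cw["Estimate"]),
      within_se = unname(cw["Std. Error"]),
      within_p = unname(cw["Pr(>|t|)"]),
      pooled_slope = unname(cp["Estimate"]),
      pooled_se = unname(cp["Std. Error"]),
      pooled_p = unname(cp["Pr(>|t|)"]),
      interaction_p = interaction_p,
      interaction_warning = isTRUE(interaction_p < 0.05),
      n = length(M)
    ),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Within-group slope: %.3f (SE %.3f, p = %.3g)\n",
              x$within_slope, x$within_se, x$within_p))
  cat(sprintf("Pooled slope (groups ignored): %.3f (p = %.3g)\n",
              x$pooled_slope, x$pooled_p))
  if (x$interaction_warning) {
    cat("Warning: group x mediator interaction p =",
        format(x$interaction_p, digits = 3),
        "- common-slope ANCOVA may be inappropriate\n")
  }
  invisible(x)
}

#' Flag an ecological-fallacy pattern
#'
#' Reports the pooled and within-group slopes side by side and raises a
#' flag when the pooled (groups-ignored) association is significant while
#' the within-group association is not — the situation where a between-
#' group offset on both axes manufactures an individual-level-looking
#' correlation that the data do not support within groups.
#'
#' @param result An `association_result`.
#' @param alpha Significance threshold for both tests. Default 0.05.
#' @return A list: `flag`, `pooled_slope`, `pooled_p`, `within_slope`,
#'   `within_p`, `message`.
#' @export
ecological_gap <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "association_result"))
  flag <- result$pooled_p < alpha && result$within_p >= alpha
  msg <- if (flag) {
    paste0("Pooled association is significant (p = ",
           format(result$pooled_p, digits = 3),
           ") but the within-group association is not (p = ",
           format(result$within_p, digits = 3),
           "): the pooled slope reflects group differences, not an ",
           "individual-level mediator-behaviour relationship.")
  } else {
    "Pooled and within-group associations agree in significance."
  }
  list(flag = flag,
       pooled_slope = result$pooled_slope, pooled_p = result$pooled_p,
       within_slope = result$within_slope, within_p = result$within_p,
       message = msg)
}
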