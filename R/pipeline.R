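#' Run the full mediation meta-analysis pipeline
#'
#' For each study: standardise (logit-transforming percent-bounded
#' outcomes), fit the Bayesian mediation model, orient the effects so that
#' positive always means better performance, and extract the indirect
#' (mediator-transmitted) and direct (all-other-mechanisms) estimates plus
#' the within-group association diagnostic. Across studies: keep the most
#' precise estimate per study and pool the indirect and the direct family
#' in two independent random-effects meta-analyses, reporting the percent
#' of the pooled total effect attributable to the mediator.
#'
#' Studies that fail their preconditions (too few animals, constant
#' mediator, more than two groups, ...) are recorded as skipped with the
#' error message and the run continues.
#'
#' @param studies List of `study_dataset` objects (see [read_study_csv()],
#'   [generate_study()]).
#' @param config A [mediation_config()]. Per-study fits are seeded as
#'   `config$seed + study index` when a seed is set, so the whole report is
#'   reproducible from one integer.
#' @param clamp,epsilon Passed to [prepare_study()] for percent-bounded
#'   outcomes.
#' @return Object of class `analysis_report`: `per_study` (data frame, one
#'   row per study x quantity), `association` (data frame), `combined`
#'   (named list of `meta_result` for `indirect` and `direct`),
#'   `percent_contribution`, `skipped` (data frame), `provenance`.
#' @export
run_full_analysis <- function(studies, config = mediation_config(seed = 1L),
                              clamp = FALSE, epsilon = 0.005) {
  if (length(studies) == 0L) {
    stop("empty-input error: no studies supplied", call. = FALSE)
  }
  stopifnot(all(vapply(studies, inherits, logical(1L), "study_dataset")))

  per_study <- list()
  assoc_rows <- list()
  skipped <- list()
  rhat_max <- c()
  for (i in seq_along(studies)) {
    ds <- studies[[i]]
    sid <- ds$meta$study_id
    res <- tryCatch({
      std <- prepare_study(ds, clamp = clamp, epsilon = epsilon)
      cfg <- config
      if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + i
      post <- fit_mediation(std, cfg)
      post <- orient_effects(post)
      assoc <- within_group_association(std)
      list(post = post, assoc = assoc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(study_id = sid, reason = conditionMessage(res))
      next
    }
    per_study[[length(per_study) + 1L]] <- rbind(
      effect_estimate(res$post, "indirect"),
      effect_estimate(res$post, "direct")
    )
    rhat_max[sid] <- max(res$post$rhat, na.rm = TRUE)
    assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
      study_id = sid,
      within_slope = res$assoc$within_slope,
      within_p = res$assoc$within_p,
      pooled_slope = res$assoc$pooled_slope,
      pooled_p = res$assoc$pooled_p,
      ecological_flag = ecological_gap(res$assoc)$flag,
      interaction_warning = res$assoc$interaction_warning,
      converged = res$post$converged
    )
  }
  if (length(per_study) == 0L) {
    stop("empty-input error: no study passed its preconditions",
         call. = FALSE)
  }
  estimates <- do.call(rbind, per_study)
  association <- do.call(rbind, assoc_rows)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(study_id = character(), reason = character())

  combined <- lapply(c(indirect = "indirect", direct = "direct"),
                     function(q) {
    sel <- select_most_precise(estimates[estimates$quantity == q, ])
    meta_analysis(sel)
  })
  percent <- percent_mediated(combined$indirect$pooled,
                              combined$direct$pooled)

  structure(
    list(
      per_study = estimates,
      association = association,
      combined = combined,
      percent_contribution = percent,
      rhat_max = rhat_max,
      skipped = skipped,
      provenance = list(
        config = unclass(config),
        n_studies = length(studies),
        n_analysed = length(unique(estimates$study_id)),
        r_version = as.character(getRversion()),
        package_version = as.character(utils::packageVersion("mediameta"))
      )
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Mediation meta-analysis of", x$provenance$n_analysed, "studies",
      if (nrow(x$skipped)) paste0("(", nrow(x$skipped), " skipped)"), "\n\n")
  cat("Mediated (indirect) effect:\n"); print(x$combined$indirect)
  cat("\nOther mechanisms (direct) effect:\n"); print(x$combined$direct)
  cat(sprintf("\nMediator contribution to the pooled total effect: %.1f%%\n",
              x$percent_contribution))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Produces `forest.csv` (one row per study per effect family plus a
#' combined row per family, suitable for drawing a forest plot),
#' `report.json` (all numerics at full precision) and `log.txt` (skipped
#' studies, sign flips, convergence warnings).
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (nrow(report$per_study) == 0L) {
    stop("empty-input error: report contains no per-study estimates",
         call. = FALSE)
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) {
    stop("I/O error: cannot create output directory ", out_dir,
         call. = FALSE)
  }

  # one row per study, indirect and direct side by side; then one combined
  # (diamond) row per effect family
  wide <- function(q) {
    sub <- report$per_study[report$per_study$quantity == q,
                            c("study_id", "y", "v", "ci_low", "ci_high")]
    names(sub)[-1L] <- paste0(q, "_", names(sub)[-1L])
    sub
  }
  forest <- merge(wide("indirect"), wide("direct"), by = "study_id",
                  sort = FALSE)
  forest <- cbind(row_type = "study", forest)
  for (q in names(report$combined)) {
    m <- report$combined[[q]]
    row <- forest[1L, ]
    row[1L, ] <- NA
    row$row_type <- paste0("combined_", q)
    row$study_id <- "combined"
    row[[paste0(q, "_y")]] <- m$pooled
    row[[paste0(q, "_v")]] <- m$se^2
    row[[paste0(q, "_ci_low")]] <- m$ci_low
    row[[paste0(q, "_ci_high")]] <- m$ci_high
    forest <- rbind(forest, row)
  }
  forest_path <- file.path(out_dir, "forest.csv")
  utils::write.csv(forest, forest_path, row.names = FALSE)

  json_path <- file.path(out_dir, "report.json")
  payload <- list(
    per_study = report$per_study,
    association = report$association,
    combined = lapply(report$combined, unclass),
    percent_contribution = report$percent_contribution,
    skipped = report$skipped,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  log_path <- file.path(out_dir, "log.txt")
  lines <- c(
    sprintf("studies analysed: %d", report$provenance$n_analysed),
    sprintf("studies skipped: %d", nrow(report$skipped)),
    if (nrow(report$skipped))
      sprintf("  skipped %s: %s", report$skipped$study_id,
              report$skipped$reason),
    sprintf("sign flips applied: %d",
            sum(report$per_study$sign_flipped) / 2),
    sprintf("max R-hat across studies: %.4f", max(report$rhat_max)),
    if (any(!report$association$converged))
      sprintf("convergence warning in: %s",
              paste(report$association$study_id[!report$association$converged],
                    collapse = ", ")),
    if (any(report$association$interaction_warning))
      sprintf("group x mediator interaction warning in: %s",
              paste(report$association$study_id[
                report$association$interaction_warning], collapse = ", "))
  )
  writeLines(lines, log_path)

  invisible(c(forest = forest_path, json = json_path, log = log_path))
}
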