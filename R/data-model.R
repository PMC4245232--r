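#' Study metadata
#'
#' Declares what a study's numbers mean: which group is the untreated
#' control, whether a *higher* or *lower* behavioural score indicates better
#' performance, and whether the outcome lives on a linear scale or is a
#' percentage bounded in (0, 100). Orientation and scale are always declared
#' by the analyst, never inferred from the data.
#'
#' @param study_id Opaque study label (e.g. a PubMed ID).
#' @param control_group Label of the control group as it appears in the data.
#' @param outcome_orientation `"higher_is_better"` or `"lower_is_better"`.
#'   Behavioural tests differ: escape latency in the Morris water maze is
#'   better when *lower*, time in the open arms is better when *higher*.
#' @param outcome_scale `"linear"` or `"percent_bounded"`. Percent-bounded
#'   outcomes (e.g. percent time freezing) are logit-transformed before
#'   standardisation so a normal linear model applies.
#' @param species_strain,behaviour_test,mediator_marker Free-text descriptors
#'   (e.g. `"C57BL/6"`, `"MWM"`, `"BrdU"`); informational only.
#' @param primary_outcomes Optional character vector giving the declared
#'   order of outcome labels, used to break ties when selecting the most
#'   precise estimate per study.
#' @return An object of class `study_meta`.
#' @export
study_meta <- function(study_id,
                       control_group,
                       outcome_orientation = c("higher_is_better", "lower_is_better"),
                       outcome_scale = c("linear", "percent_bounded"),
                       species_strain = NA_character_,
                       behaviour_test = NA_character_,
                       mediator_marker = NA_character_,
                       primary_outcomes = character()) {
  outcome_orientation <- match.arg(outcome_orientation)
  outcome_scale <- match.arg(outcome_scale)
  stopifnot(is.character(study_id) || is.numeric(study_id),
            length(study_id) == 1L,
            length(control_group) == 1L)
  structure(
    list(
      study_id = as.character(study_id),
      control_group = as.character(control_group),
      outcome_orientation = outcome_orientation,
      outcome_scale = outcome_scale,
      species_strain = species_strain,
      behaviour_test = behaviour_test,
      mediator_marker = mediator_marker,
      primary_outcomes = as.character(primary_outcomes)
    ),
    class = "study_meta"
  )
}

#' Assemble a study dataset from animal-level records
#'
#' @param meta A [study_meta()] object.
#' @param records A data frame with columns `animal_id`, `group`, `mediator`
#'   (assay units, e.g. cells or cells/mm3) and `outcome` (task units).
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(meta, records) {
  stopifnot(inherits(meta, "study_meta"), is.data.frame(records))
  required <- c("animal_id", "group", "mediator", "outcome")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$group <- as.character(records$group)

  for (col in c("mediator", "outcome")) {
    vals <- records[[col]]
    if (!is.numeric(vals)) {
      suppressWarnings(num <- as.numeric(as.character(vals)))
      bad <- which(is.na(num))
      if (length(bad) > 0L) {
        stop(sprintf("parse error: non-numeric %s on row %d", col, bad[1L]),
             call. = FALSE)
      }
      records[[col]] <- num
    } else if (anyNA(vals) || any(!is.finite(vals))) {
      bad <- which(is.na(vals) | !is.finite(vals))
      stop(sprintf("parse error: non-finite %s on row %d", col, bad[1L]),
           call. = FALSE)
    }
  }

  groups <- unique(records$group)
  if (length(groups) < 2L) {
    stop("design error: a study needs at least 2 groups, found ",
         length(groups), call. = FALSE)
  }
  if (!meta$control_group %in% groups) {
    stop("design error: declared control group '", meta$control_group,
         "' not present in the data (groups: ",
         paste(groups, collapse = ", "), ")", call. = FALSE)
  }
  counts <- table(records$group)
  if (any(counts < 3L)) {
    stop("design error: every group needs >= 3 animals; smallest has ",
         min(counts), call. = FALSE)
  }
  if (stats::sd(records$mediator) == 0) {
    stop("degenerate-data error: mediator is constant across the study",
         call. = FALSE)
  }

  structure(list(meta = meta, records = records), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Study", x$meta$study_id, "-", nrow(x$records), "animals in",
      length(unique(x$records$group)), "groups\n")
  cat("  control:", x$meta$control_group,
      "| orientation:", x$meta$outcome_orientation,
      "| scale:", x$meta$outcome_scale, "\n")
  invisible(x)
}

#' Read an animal-level study table from CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `animal_id`, `group`,
#' `mediator`, `outcome` (decimal point `"."`). Validation — group levels,
#' numeric parsing, minimum group sizes — is delegated to [study_dataset()].
#'
#' @param path Path to the CSV file.
#' @param meta A [study_meta()] object describing the study.
#' @return A `study_dataset`.
#' @export
read_study_csv <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  study_dataset(meta, records)
}

#' Logit transform for percent-bounded outcomes
#'
#' Maps percentages in (0, 100) to the real line via `log(p/(1-p))` with
#' `p = value/100`, so that normal linear models can be fit to bounded
#' behavioural outcomes such as percent time freezing.
#'
#' Boundary values (exactly 0 or 100) are rejected by default, since
#' silently clamping them can bias estimates. With `clamp = TRUE`,
#' proportions are clamped into `[epsilon, 1 - epsilon]` first.
#'
#' @param values Numeric vector of percentages.
#' @param clamp Clamp boundary values instead of erroring? Default `FALSE`.
#' @param epsilon Clamping bound on the proportion scale. Default `0.005`.
#' @return Numeric vector on the logit scale.
#' @seealso [inv_logit_percent()]
#' @export
logit_percent <- function(values, clamp = FALSE, epsilon = 0.005) {
  stopifnot(is.numeric(values))
  p <- values / 100
  if (clamp) {
    p <- pmin(pmax(p, epsilon), 1 - epsilon)
  } else if (any(p <= 0 | p >= 1)) {
    stop("domain error: percent values must lie strictly in (0, 100); ",
         "use clamp = TRUE to clamp boundary values", call. = FALSE)
  }
  log(p / (1 - p))
}

#' Inverse logit back to the percent scale
#'
#' @param x Numeric vector on the logit scale.
#' @return Percentages in (0, 100): `100 * exp(x) / (1 + exp(x))`.
#' @export
inv_logit_percent <- function(x) {
  100 * stats::plogis(x)
}

#' Standardise to z-scores
#'
#' Centers and scales to mean 0 and *sample* standard deviation 1
#' (n - 1 denominator), preserving order.
#'
#' @param values Numeric vector, length >= 2, not all equal.
#' @return Z-scores.
#' @export
standardize <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate-data error: cannot standardise a constant vector",
         call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Prepare a study for mediation analysis
#'
#' Converts a two-group `study_dataset` into the model-ready triplet
#' (T, M, Y): a 0/1 treatment indicator (control = 0), the standardised
#' mediator and the standardised outcome. Standardisation is pooled across
#' both groups within the study — per-group standardisation would erase the
#' treatment-to-mediator path. Percent-bounded outcomes are
#' logit-transformed before standardisation. Outcome orientation is *not*
#' applied here; signs are reversed at the estimate level after fitting
#' (see [orient_effects()]).
#'
#' @param dataset A `study_dataset` with exactly two groups.
#' @param clamp,epsilon Passed to [logit_percent()] for percent-bounded
#'   outcomes.
#' @return An object of class `standardized_study` with fields `T`, `M`,
#'   `Y`, `meta`, `animal_id`.
#' @export
prepare_study <- function(dataset, clamp = FALSE, epsilon = 0.005) {
  stopifnot(inherits(dataset, "study_dataset"))
  rec <- dataset$records
  meta <- dataset$meta
  groups <- unique(rec$group)
  if (length(groups) != 2L) {
    stop("unsupported-design error: mediation model supports exactly 2 ",
         "groups (one treated, one control); this study has ",
         length(groups), call. = FALSE)
  }
  trt <- as.integer(rec$group != meta$control_group)

  y_raw <- rec$outcome
  if (meta$outcome_scale == "percent_bounded") {
    y_raw <- logit_percent(y_raw, clamp = clamp, epsilon = epsilon)
  }

  structure(
    list(
      T = trt,
      M = standardize(rec$mediator),
      Y = standardize(y_raw),
      meta = meta,
      animal_id = rec$animal_id
    ),
    class = "standardized_study"
  )
}

#' @export
print.standardized_study <- function(x, ...) {
  cat("Standardized study", x$meta$study_id, "-", length(x$T), "animals (",
      sum(x$T == 0L), "control /", sum(x$T == 1L), "treated )\n")
  invisible(x)
}
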