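#' Read and validate a patient-level cohort table
#'
#' Reads a CSV of resected patients, maps its columns onto the canonical
#' schema, validates every record, and returns a cohort stratified by T
#' stage. Each record describes one patient: T stage (1-4), the number of
#' lymph nodes examined at surgery, the number found positive, and
#' disease-specific survival (months plus an event indicator). Additional
#' columns are carried through untouched as annotations.
#'
#' Validation enforces: `0 <= nodes_positive <= nodes_examined`,
#' `nodes_examined >= 1` (a patient with no node examined cannot be
#' nodally staged and carries no information for the model), and
#' `t_stage` in 1-4. Offending rows raise an error naming them.
#'
#' @param path Path to a CSV file with a header row (UTF-8, comma
#'   separated).
#' @param column_map Named character vector mapping canonical names
#'   (`patient_id`, `t_stage`, `nodes_examined`, `nodes_positive`,
#'   `survival_months`, `event`) to the file's column names. Defaults to
#'   the identity mapping, so a file already using canonical headers
#'   needs no map.
#' @return An `nss_cohort`: a data.frame with the canonical columns first,
#'   pass-through covariates after, carrying class `"nss_cohort"`.
#' @seealso [as_cohort()] to validate an in-memory data.frame,
#'   [write_cohort()] for the inverse operation.
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(raw, column_map = column_map)
}

#' Validate a data.frame as a cohort
#'
#' @param x A data.frame holding one row per patient.
#' @inheritParams read_cohort
#' @return An `nss_cohort` data.frame.
#' @export
as_cohort <- function(x, column_map = NULL) {
  canonical <- c("patient_id", "t_stage", "nodes_examined",
                 "nodes_positive", "survival_months", "event")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
      stop("column_map must be a named vector: canonical name -> file column")
    }
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown)) {
      stop("column_map has unknown canonical names: ",
           paste(unknown, collapse = ", "))
    }
    map[names(column_map)] <- unname(column_map)
  }
  missing_cols <- setdiff(unname(map), names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }

  out <- data.frame(
    patient_id      = as.character(x[[map["patient_id"]]]),
    t_stage         = suppressWarnings(as.integer(x[[map["t_stage"]]])),
    nodes_examined  = suppressWarnings(as.integer(x[[map["nodes_examined"]]])),
    nodes_positive  = suppressWarnings(as.integer(x[[map["nodes_positive"]]])),
    survival_months = suppressWarnings(as.numeric(x[[map["survival_months"]]])),
    event           = suppressWarnings(as.integer(x[[map["event"]]])),
    stringsAsFactors = FALSE
  )
  extras <- setdiff(names(x), unname(map))
  if (length(extras)) out <- cbind(out, x[extras])

  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop("invalid record(s) at row ", paste(utils::head(idx, 5), collapse = ", "),
           ": ", what, call. = FALSE)
    }
  }
  bad(is.na(out$t_stage) | !(out$t_stage %in% 1:4),
      "t_stage must be an integer in 1..4")
  bad(is.na(out$nodes_examined) | out$nodes_examined < 1,
      "nodes_examined must be an integer >= 1")
  bad(is.na(out$nodes_positive) | out$nodes_positive < 0,
      "nodes_positive must be a non-negative integer")
  bad(out$nodes_positive > out$nodes_examined,
      "nodes_positive exceeds nodes_examined")
  bad(is.na(out$survival_months) | out$survival_months < 0,
      "survival_months must be a non-negative number")
  bad(is.na(out$event) | !(out$event %in% c(0L, 1L)),
      "event must be 0 (censored) or 1 (death from disease)")

  class(out) <- c("nss_cohort", "data.frame")
  out
}

#' Write a cohort back to CSV
#'
#' Exact inverse of [read_cohort()] under canonical headers: reading the
#' written file reproduces every record and value.
#'
#' @param cohort An `nss_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "nss_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Drop patients below a minimum follow-up
#'
#' Removes records whose survival time is shorter than
#' `min_followup_months` (very short follow-up reflects perioperative
#' events rather than nodal disease burden). The number removed is
#' reported via a message; an empty result is allowed but warned about.
#'
#' @param cohort An `nss_cohort`.
#' @param min_followup_months Non-negative threshold in months
#'   (default 1).
#' @return The filtered `nss_cohort`.
#' @export
apply_exclusions <- function(cohort, min_followup_months = 1) {
  stopifnot(inherits(cohort, "nss_cohort"), min_followup_months >= 0)
  keep <- cohort$survival_months >= min_followup_months
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " patient(s) removed with follow-up < ",
            min_followup_months, " months")
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all patients excluded; cohort is empty")
  class(out) <- c("nss_cohort", "data.frame")
  out
}

#' Raw lymph-node-metastasis rate
#'
#' Fraction of patients with at least one positive node (pN+) among all
#' patients of a stratum, before any false-negative correction.
#'
#' @param cohort An `nss_cohort`.
#' @param t_stage A single T stage 1-4, or `"all"` for the pooled rate.
#' @return A proportion in `[0, 1]`, at full precision (round only for
#'   presentation).
#' @export
raw_lnm_rate <- function(cohort, t_stage = "all") {
  stopifnot(inherits(cohort, "nss_cohort"))
  rows <- if (identical(t_stage, "all")) {
    cohort
  } else {
    stopifnot(t_stage %in% 1:4)
    cohort[cohort$t_stage == t_stage, , drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    stop("LNM rate undefined: stratum ", t_stage, " is empty")
  }
  mean(rows$nodes_positive >= 1L)
}

#' Per-stratum patient tallies
#'
#' Counts, for one T stage and each observed number of examined nodes e,
#' the node-positive patients `tp` (including those with every examined
#' node positive) and the node-negative patients `n`. These tallies are
#' the inputs of the false-negative count estimate and the adjusted-rate
#' denominator.
#'
#' @param cohort An `nss_cohort`.
#' @param t_stage A single T stage present in the cohort.
#' @return A data.frame with columns `e`, `tp`, `n`, one row per observed
#'   `e`, ascending.
#' @export
stratum_tallies <- function(cohort, t_stage) {
  stopifnot(inherits(cohort, "nss_cohort"), t_stage %in% 1:4)
  rows <- cohort[cohort$t_stage == t_stage, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no patients in T stage ", t_stage)
  e_vals <- sort(unique(rows$nodes_examined))
  pos <- rows$nodes_positive >= 1L
  data.frame(
    e  = e_vals,
    tp = vapply(e_vals, function(e) sum(rows$nodes_examined == e & pos), 0L),
    n  = vapply(e_vals, function(e) sum(rows$nodes_examined == e & !pos), 0L)
  )
}

#' @export
print.nss_cohort <- function(x, ...) {
  stages <- sort(unique(x$t_stage))
  cat("Nodal staging cohort: ", nrow(x), " patients, T stages ",
      paste(stages, collapse = ","), "\n", sep = "")
  for (t in stages) {
    rows <- x[x$t_stage == t, ]
    cat(sprintf("  T%d: n=%d (pN0 %d, pN+ %d), median e=%g\n",
                t, nrow(rows), sum(rows$nodes_positive == 0L),
                sum(rows$nodes_positive >= 1L),
                stats::median(rows$nodes_examined)))
  }
  invisible(x)
}
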