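#' Construct a cohort table
#'
#' Thin wrapper around a data frame of numeric columns, carrying the
#' per-variable metadata of a [block_ordering()] and a flag recording whether
#' the natural-log transform has been applied.
#'
#' @param data A data frame with one numeric column per declared variable.
#' @param ordering A [block_ordering()] whose variables must all be present.
#' @param log_applied Has [log_transform_cohort()] already been applied?
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(data, ordering, log_applied = FALSE) {
  missing_cols <- setdiff(ordering_names(ordering), names(data))
  if (length(missing_cols))
    stop("cohort is missing declared column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0L) stop("cohort has zero rows", call. = FALSE)
  data <- data[, ordering_names(ordering), drop = FALSE]
  for (nm in names(data)) data[[nm]] <- as.numeric(data[[nm]])
  structure(list(data = data, ordering = ordering,
                 log_applied = isTRUE(log_applied)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d rows, %d variables (%s scale)\n",
              nrow(x$data), ncol(x$data),
              if (x$log_applied) "natural-log" else "original"))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

#' Read a cohort CSV against a declared block ordering
#'
#' Reads a header CSV, keeps the declared columns (warning about extras),
#' coerces non-numeric cells to missing, and reports per-column missing
#' counts in the `missing_counts` attribute.
#'
#' @param path CSV file path.
#' @param ordering A [block_ordering()] declaring the expected columns.
#' @return A `cohort_table` on the original scale, with attributes
#'   `missing_counts` (named integer) and `ignored_columns` (character).
#' @export
read_cohort <- function(path, ordering) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  declared <- ordering_names(ordering)
  missing_cols <- setdiff(declared, names(raw))
  if (length(missing_cols))
    stop("cohort file lacks declared column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(raw), declared)
  if (length(extra))
    warning("ignoring undeclared column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  dat <- raw[declared]
  for (nm in declared) {
    v <- dat[[nm]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(as.character(v)))
    dat[[nm]] <- v
  }
  tab <- cohort_table(dat, ordering)
  attr(tab, "missing_counts") <-
    vapply(dat, function(v) sum(is.na(v)), integer(1))
  attr(tab, "ignored_columns") <- extra
  tab
}

#' Apply the natural-log transform to a cohort
#'
#' Every variable flagged `log_transform` in the ordering is replaced by its
#' natural logarithm. All variables of the shipped configurations are
#' log-transformed, so that a partial regression coefficient reads as a
#' percent change in the response per percent change in the regressor.
#'
#' @param t A `cohort_table` with `log_applied = FALSE`.
#' @return The transformed `cohort_table` (`log_applied = TRUE`).
#' @export
log_transform_cohort <- function(t) {
  stopifnot(inherits(t, "cohort_table"))
  if (t$log_applied) stop("log transform already applied", call. = FALSE)
  for (nm in names(t$data)) {
    spec <- t$ordering$variables[[nm]]
    v <- t$data[[nm]]
    if (spec$positive_required) {
      bad <- which(!is.na(v) & v <= 0)
      if (length(bad))
        stop(sprintf("non-positive value in column '%s' at row %d (value %g)",
                     nm, bad[[1L]], v[bad[[1L]]]), call. = FALSE)
    }
    if (spec$log_transform) t$data[[nm]] <- log(v)
  }
  t$log_applied <- TRUE
  t
}

#' Restrict a cohort to complete cases over a set of variables
#'
#' Complete-case filtering is applied per fitted model, not listwise over the
#' whole table, so each node model can use every row observed for its own
#' variables.
#'
#' @param t A `cohort_table`.
#' @param vars Character vector of variable names (empty set keeps all rows).
#' @return The filtered `cohort_table` (row order preserved; idempotent).
#' @export
complete_cases <- function(t, vars) {
  stopifnot(inherits(t, "cohort_table"))
  bad <- setdiff(vars, names(t$data))
  if (length(bad))
    stop("unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(vars) == 0L) return(t)
  keep <- !Reduce(`|`, lapply(t$data[vars], is.na))
  t$data <- t$data[keep, , drop = FALSE]
  t
}

#' Per-variable descriptive statistics on the original scale
#'
#' @param t A `cohort_table` (original scale).
#' @return A data frame with one row per variable: `variable`, `n`, `mean`,
#'   `sd`, `min`, `max`; missing values are excluded per variable.
#' @export
descriptives <- function(t) {
  stopifnot(inherits(t, "cohort_table"))
  rows <- lapply(names(t$data), function(nm) {
    v <- t$data[[nm]][!is.na(t$data[[nm]])]
    data.frame(variable = nm, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else if (length(v)) 0 else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split values into tertiles
#'
#' Boundaries are the empirical 1/3 and 2/3 quantiles (type-7, linear
#' interpolation). Values at or below the lower boundary are `low`, at or
#' below the upper boundary `mid`, above it `high`; ties fall to the lower
#' group. Missing values stay missing.
#'
#' @param values Numeric vector with at least 3 non-missing values.
#' @return A list with `labels` (factor low/mid/high) and `boundaries`
#'   (length-2 numeric). A degenerate boundary (all values equal) labels
#'   everything `low` with a warning.
#' @export
tertile_split <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3L)
    stop("need at least 3 non-missing values for tertiles", call. = FALSE)
  b <- stats::quantile(values[ok], probs = c(1, 2) / 3, names = FALSE, type = 7)
  if (b[1L] == b[2L])
    warning("degenerate tertile boundaries (ties at the cut points)",
            call. = FALSE)
  lab <- rep(NA_character_, length(values))
  lab[ok & values <= b[1L]] <- "low"
  lab[ok & values > b[1L] & values <= b[2L]] <- "mid"
  lab[ok & values > b[2L]] <- "high"
  list(labels = factor(lab, levels = c("low", "mid", "high")),
       boundaries = b)
}

#' Geometric mean
#'
#' `exp(mean(log(x)))`; the natural summary for a model fitted on the log
#' scale, since the model's estimated mean of log data back-transforms to a
#' geometric mean of the original data.
#'
#' @param values Positive numeric vector (missing values dropped).
#' @return The geometric mean.
#' @export
geometric_mean <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no non-missing values", call. = FALSE)
  if (any(v <= 0)) stop("geometric mean requires positive values", call. = FALSE)
  exp(mean(log(v)))
}
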