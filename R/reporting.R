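#' Tertile-by-tertile geometric-mean grid for a two-way interaction
#'
#' Splits the two factors into tertiles of their observed distributions and
#' reports the geometric mean of the outcome in each of the 3 x 3 cells,
#' the display the interaction plots of the analysis are built from (the
#' model estimates means of log data, which back-transform to geometric
#' means). Empty cells are reported as `NA` and flagged, never interpolated.
#'
#' @param t A `cohort_table` on the original scale.
#' @param outcome Positive outcome variable name.
#' @param f1 Factor defining the grid rows.
#' @param f2 Factor defining the grid columns.
#' @return An object of class `tertile_grid`: `outcome`, `factor_rows`,
#'   `factor_cols`, `boundaries` (list of two cut-point pairs on the
#'   original scale), `cells` (3 x 3 geometric means), `counts` (3 x 3 cell
#'   sizes), `degenerate` (flag for empty rows/columns).
#' @export
tertile_grid <- function(t, outcome, f1, f2) {
  stopifnot(inherits(t, "cohort_table"))
  if (t$log_applied)
    stop("tertile grids are computed on the original scale", call. = FALSE)
  tcc <- complete_cases(t, c(outcome, f1, f2))
  dat <- tcc$data
  s1 <- tertile_split(dat[[f1]])
  s2 <- tertile_split(dat[[f2]])
  lv <- c("low", "mid", "high")
  cells <- counts <- matrix(NA_real_, 3L, 3L, dimnames = list(lv, lv))
  for (i in lv) for (j in lv) {
    sel <- which(s1$labels == i & s2$labels == j)
    counts[i, j] <- length(sel)
    if (length(sel)) cells[i, j] <- geometric_mean(dat[[outcome]][sel])
  }
  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (degenerate)
    warning("degenerate tertile grid: an entire row or column is empty",
            call. = FALSE)
  structure(list(outcome = outcome, factor_rows = f1, factor_cols = f2,
                 boundaries = list(rows = s1$boundaries, cols = s2$boundaries),
                 cells = cells, counts = counts, n = nrow(dat),
                 degenerate = degenerate),
            class = "tertile_grid")
}

#' @export
print.tertile_grid <- function(x, ...) {
  cat(sprintf("Geometric means of %s by tertiles of %s (rows) x %s (cols), n = %d\n",
              x$outcome, x$factor_rows, x$factor_cols, x$n))
  print(signif(x$cells, 4))
  invisible(x)
}

#' Percent contrast between two grid cells
#'
#' @param g A [tertile_grid()].
#' @param cell_a,cell_b Length-2 vectors (row, col), by index or by
#'   `"low"/"mid"/"high"` label; the contrast is a vs b.
#' @return `100 * (cells[a] / cells[b] - 1)`.
#' @export
grid_contrast <- function(g, cell_a, cell_b) {
  va <- g$cells[cell_a[[1L]], cell_a[[2L]]]
  vb <- g$cells[cell_b[[1L]], cell_b[[2L]]]
  if (is.na(va) || is.na(vb))
    stop("empty grid cell in contrast", call. = FALSE)
  100 * (va / vb - 1)
}

tertile_grid_to_list <- function(g) {
  list(outcome = g$outcome, factor_rows = g$factor_rows,
       factor_cols = g$factor_cols,
       boundaries = g$boundaries, cells = g$cells, counts = g$counts,
       n = g$n, degenerate = g$degenerate)
}

#' Run the full analysis pipeline on a cohort file
#'
#' Reads the cohort and the block-ordering configuration, computes
#' descriptives, fits the sequence of regressions, builds a tertile grid for
#' every retained interaction (plus any explicitly requested), runs the
#' requested partition queries, and assembles everything into a report. With
#' `out_dir` the report is serialized as JSON plus TSV tables and a DOT
#' graph; the JSON carries no timestamps, so identical inputs give
#' byte-identical output.
#'
#' @param data_path CSV cohort file.
#' @param config_path YAML/JSON block-ordering configuration.
#' @param alpha Significance level for retention (default 0.05).
#' @param grids Optional list of `c(outcome, f1, f2)` grid requests, in
#'   addition to the automatic one-per-retained-interaction grids.
#' @param queries Optional list of partition queries, each
#'   `list(y =, xs =, given =)`.
#' @param cfg A [fit_config()]; its `alpha` is overridden by `alpha`.
#' @param out_dir Optional output directory.
#' @return An object of class `pipeline_report` with elements
#'   `descriptives`, `fit`, `grids`, `queries`, `provenance`.
#' @export
run_pipeline <- function(data_path, config_path, alpha = 0.05, grids = list(),
                         queries = list(), cfg = fit_config(alpha = alpha),
                         out_dir = NULL) {
  cfg$alpha <- alpha
  ordering <- read_ordering(config_path)
  cohort <- read_cohort(data_path, ordering)
  desc <- descriptives(cohort)
  fit <- fit_sequence(cohort, ordering, cfg)
  auto_grids <- list()
  for (mod in fit$models) {
    for (tm in mod$terms) {
      if (tm$kind == "interaction")
        auto_grids[[length(auto_grids) + 1L]] <-
          c(mod$response, tm$variables[1L], tm$variables[2L])
    }
  }
  all_grids <- c(auto_grids, grids)
  grid_objs <- lapply(all_grids, function(gq)
    tertile_grid(cohort, gq[[1L]], gq[[2L]], gq[[3L]]))
  tl <- log_transform_cohort(cohort)
  query_res <- lapply(queries, function(q) {
    res <- partition_query(tl, q$y, q$xs, q$given %||% character(0))
    list(y = q$y, xs = q$xs, given = q$given %||% character(0),
         n = attr(res, "n"), r_squared = attr(res, "r_squared"),
         table = res)
  })
  report <- structure(
    list(descriptives = desc, fit = fit, grids = grid_objs,
         queries = query_res,
         provenance = list(
           data_path = basename(data_path),
           config = yaml::as.yaml(yaml::read_yaml(config_path)),
           alpha = alpha,
           seed = cfg$seed,
           package_version = as.character(utils::packageVersion("seqregraph")))),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n===============\n")
  cat(sprintf("Cohort: %d rows, %d variables\n", max(x$descriptives$n),
              nrow(x$descriptives)))
  print(x$fit)
  if (length(x$grids))
    cat(sprintf("%d tertile grid(s), %d partition query(ies)\n",
                length(x$grids), length(x$queries)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (master), `descriptives.tsv`, `models.tsv`
#' (coefficient table) and `graph.dot`.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- list(
    provenance = report$provenance,
    descriptives = report$descriptives,
    fit = jsonlite::parse_json(sequence_fit_json(report$fit)),
    grids = lapply(report$grids, tertile_grid_to_list),
    queries = report$queries)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"),
             file.path(out_dir, "report.json"))
  utils::write.table(report$descriptives,
                     file.path(out_dir, "descriptives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(coefficient_table(report$fit),
                     file.path(out_dir, "models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  annotations <- list()
  for (mod in report$fit$models) {
    for (i in seq_along(mod$terms)) {
      tm <- mod$terms[[i]]
      if (tm$kind != "main") next
      annotations[[paste0(tm$variables, "->", mod$response)]] <-
        sprintf("%s (%s, %s); p=%s", signif(mod$beta[i], 2),
                signif(mod$ci_low[i], 2), signif(mod$ci_high[i], 2),
                signif(mod$p[i], 2))
    }
  }
  writeLines(to_dot(report$fit$graph, annotations),
             file.path(out_dir, "graph.dot"))
  invisible(out_dir)
}
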