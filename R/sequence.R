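#' Test a within-box association between two responses
#'
#' Two responses in the same box are joined by a dashed edge when they remain
#' associated after controlling for their combined set of explanatory
#' variables. The test computes the partial correlation of the two residual
#' vectors from least-squares fits of each response on the combined
#' conditioning design, with a t-transform on `n - k - 2` degrees of freedom
#' (`k` conditioning columns).
#'
#' @param t A log-scale `cohort_table`.
#' @param a,b Distinct response names from the same box.
#' @param combined_explanatory Either a character vector of variable names or
#'   a list of [term_spec()]s (the union of the two node models' terms).
#' @param centers Optional centering constants for product terms.
#' @return List with `pcor`, `p`, `df`, `n`.
#' @export
within_box_test <- function(t, a, b, combined_explanatory = character(0),
                            centers = NULL) {
  stopifnot(inherits(t, "cohort_table"), t$log_applied)
  if (identical(a, b)) stop("`a` and `b` must differ", call. = FALSE)
  terms <- if (is.character(combined_explanatory)) {
    lapply(combined_explanatory, function(v) term_spec("main", v))
  } else combined_explanatory
  cond_vars <- unique(unlist(lapply(terms, `[[`, "variables")))
  tcc <- complete_cases(t, c(a, b, cond_vars))
  dat <- tcc$data
  X <- build_design(dat, terms, centers = centers)
  ra <- ols_engine(dat[[a]], X)$residuals
  rb <- ols_engine(dat[[b]], X)$residuals
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("degenerate residuals (zero variance) in within-box test", call. = FALSE)
  r <- stats::cor(ra, rb)
  k <- ncol(X)
  df <- nrow(dat) - k - 2L
  if (df < 1L) stop("not enough rows for within-box test", call. = FALSE)
  tval <- r * sqrt(df / (1 - r^2))
  list(pcor = r, p = 2 * stats::pt(-abs(tval), df), df = df, n = nrow(dat))
}

#' Fit the full sequence of regressions and assemble the regression graph
#'
#' Applies the natural-log transform (if not yet applied), then fits each
#' response box in order: per response, complete cases are taken over the
#' response and its admissible candidates, a node model is selected with
#' [select_model()], and finally every same-box response pair is tested with
#' [within_box_test()] conditioning on the union of the pair's selected
#' terms. The regression graph receives an arrow into a response from every
#' variable appearing in its retained terms (including variables inside
#' interactions and quadratics), a dashed edge for every significant
#' within-box pair, and a full line for every significant context-box pair
#' (marginal correlation test).
#'
#' @param t A `cohort_table` (raw or already log-transformed).
#' @param ordering A [block_ordering()].
#' @param cfg A [fit_config()].
#' @return An object of class `sequence_fit` with elements `models` (named
#'   list of `node_model`), `dashed_tests`, `full_tests`, `graph`, `config`,
#'   `ordering`, `selection_log`.
#' @export
fit_sequence <- function(t, ordering, cfg = fit_config()) {
  stopifnot(inherits(t, "cohort_table"))
  if (!t$log_applied) t <- log_transform_cohort(t)
  models <- list()
  logs <- list()
  resp_boxes <- which(ordering$kinds == "response")
  for (b in resp_boxes) {
    for (response in ordering$boxes[[b]]) {
      cand <- candidate_terms(response, ordering)
      mod <- select_model(t, response, cand, cfg)
      models[[response]] <- mod
      sl <- attr(mod, "selection_log")
      if (nrow(sl)) logs[[response]] <- cbind(response = response, sl)
    }
  }
  dashed_rows <- list()
  dashed_edges <- NULL
  for (b in resp_boxes) {
    box_vars <- ordering$boxes[[b]]
    if (length(box_vars) < 2L) next
    for (i in seq_along(box_vars)) for (j in seq_along(box_vars)) {
      if (j <= i) next
      a <- box_vars[i]; bb <- box_vars[j]
      combined <- unique_terms(c(models[[a]]$terms, models[[bb]]$terms))
      res <- within_box_test(t, a, bb, combined)
      sig <- res$p < cfg$alpha
      dashed_rows[[length(dashed_rows) + 1L]] <-
        data.frame(a = a, b = bb, pcor = res$pcor, p = res$p, n = res$n,
                   significant = sig, stringsAsFactors = FALSE)
      if (sig) dashed_edges <- rbind(dashed_edges, c(a, bb))
    }
  }
  full_rows <- list()
  full_edges <- NULL
  for (b in which(ordering$kinds == "context")) {
    box_vars <- ordering$boxes[[b]]
    if (length(box_vars) < 2L) next
    for (i in seq_along(box_vars)) for (j in seq_along(box_vars)) {
      if (j <= i) next
      a <- box_vars[i]; bb <- box_vars[j]
      tcc <- complete_cases(t, c(a, bb))
      ct <- stats::cor.test(tcc$data[[a]], tcc$data[[bb]])
      sig <- ct$p.value < cfg$alpha
      full_rows[[length(full_rows) + 1L]] <-
        data.frame(a = a, b = bb, cor = unname(ct$estimate), p = ct$p.value,
                   significant = sig, stringsAsFactors = FALSE)
      if (sig) full_edges <- rbind(full_edges, c(a, bb))
    }
  }
  arrows <- NULL
  for (response in names(models)) {
    vars <- unique(unlist(lapply(models[[response]]$terms, `[[`, "variables")))
    for (v in vars) arrows <- rbind(arrows, c(v, response))
  }
  graph <- regression_graph(ordering, arrows = arrows, dashed = dashed_edges,
                            full = full_edges)
  structure(
    list(models = models,
         dashed_tests = if (length(dashed_rows)) do.call(rbind, dashed_rows)
                        else data.frame(),
         full_tests = if (length(full_rows)) do.call(rbind, full_rows)
                      else data.frame(),
         graph = graph, config = cfg, ordering = ordering,
         selection_log = if (length(logs)) do.call(rbind, logs)
                         else data.frame()),
    class = "sequence_fit")
}

unique_terms <- function(terms) {
  terms[!duplicated(terms_labels(terms))]
}

#' @export
print.sequence_fit <- function(x, ...) {
  cat("Sequence-of-regressions fit:", length(x$models), "node models\n")
  for (nm in names(x$models)) {
    mod <- x$models[[nm]]
    cat(sprintf("  %s ~ %s  (R^2 = %.2f, n = %d)\n", nm,
                if (length(mod$terms)) paste(terms_labels(mod$terms), collapse = " + ")
                else "1", mod$r_squared, mod$n_used))
  }
  nd <- if (nrow(x$dashed_tests)) sum(x$dashed_tests$significant) else 0L
  cat(sprintf("  %d dashed edge(s), %d arrow(s)\n", nd, nrow(x$graph$arrows)))
  invisible(x)
}

#' Tabulate a sequence fit in the style of a coefficients table
#'
#' One row per term, one column block per response, with
#' `beta (ci_low, ci_high)` strings rounded to 2 significant figures and a
#' final `R^2` row, mirroring the conventional presentation of sequences of
#' regressions.
#'
#' @param fit A `sequence_fit`.
#' @param responses Responses to include (default: all fitted).
#' @return A data frame of formatted strings.
#' @export
coefficient_table <- function(fit, responses = names(fit$models)) {
  fmt <- function(b, lo, hi)
    sprintf("%s (%s, %s)", signif(b, 2), signif(lo, 2), signif(hi, 2))
  all_terms <- unique(unlist(lapply(fit$models[responses], function(m)
    terms_labels(m$terms))))
  out <- data.frame(term = c(all_terms, "R^2"), stringsAsFactors = FALSE)
  for (resp in responses) {
    mod <- fit$models[[resp]]
    col <- rep("", length(all_terms) + 1L)
    labs <- terms_labels(mod$terms)
    for (i in seq_along(labs)) {
      col[match(labs[i], all_terms)] <-
        fmt(mod$beta[i], mod$ci_low[i], mod$ci_high[i])
    }
    col[length(col)] <- as.character(signif(mod$r_squared, 2))
    out[[resp]] <- col
  }
  out
}

node_model_to_list <- function(mod) {
  list(response = mod$response,
       terms = lapply(mod$terms, function(tm)
         list(kind = tm$kind, variables = as.list(tm$variables),
              label = tm$label)),
       beta = mod$beta, se = mod$se, ci_low = mod$ci_low,
       ci_high = mod$ci_high, p = mod$p, intercept = mod$intercept,
       r_squared = mod$r_squared, sigma = mod$sigma, n_used = mod$n_used)
}

#' Serialize a sequence fit to JSON
#'
#' @param fit A `sequence_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
sequence_fit_json <- function(fit, path = NULL) {
  obj <- list(
    alpha = fit$config$alpha,
    multiple_testing_adjustment = "none (a-priori distinct hypotheses)",
    tertile_convention = "type-7 empirical quantiles; ties to the lower group",
    models = lapply(fit$models, node_model_to_list),
    dashed_tests = fit$dashed_tests,
    full_tests = fit$full_tests,
    selection_log = fit$selection_log,
    graph = list(arrows = fit$graph$arrows, dashed = fit$graph$dashed,
                 full = fit$graph$full))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
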