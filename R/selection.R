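#' Fitting configuration for the sequence of regressions
#'
#' @param alpha Retention significance level (the study convention is 5%).
#' @param screen_interactions Screen pairwise products of retained variables?
#' @param screen_quadratics Screen squares of retained variables?
#' @param center_before_products Form products/squares from mean-centered
#'   log variables (reduces collinearity; only lower-order coefficients are
#'   reparameterized, the product coefficient itself is unchanged).
#' @param screen_scope `"retained"` screens higher-order terms built from the
#'   retained main effects only; `"all"` screens the full candidate set.
#' @param seed Seed for any resampled diagnostics (kept for reproducibility
#'   metadata; the fitting itself is deterministic).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(alpha = 0.05, screen_interactions = TRUE,
                       screen_quadratics = TRUE, center_before_products = TRUE,
                       screen_scope = c("retained", "all"), seed = 1L) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(alpha = alpha,
                 screen_interactions = isTRUE(screen_interactions),
                 screen_quadratics = isTRUE(screen_quadratics),
                 center_before_products = isTRUE(center_before_products),
                 screen_scope = match.arg(screen_scope),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Admissible candidate terms for a response
#'
#' The candidates are the main effects of every variable in a strictly later
#' box than the response (including context boxes), in box order and then
#' configuration order. Variables sharing the response's box are never
#' candidates: within-box associations are handled by [within_box_test()].
#'
#' @param response Name of a response-box variable.
#' @param ordering A [block_ordering()].
#' @return List of main-effect [term_spec()]s.
#' @export
candidate_terms <- function(response, ordering) {
  spec <- ordering$variables[[response]]
  if (is.null(spec)) stop("unknown variable: ", response, call. = FALSE)
  if (spec$box_kind != "response")
    stop("'", response, "' is a context variable, not a response", call. = FALSE)
  later <- which(seq_along(ordering$boxes) - 1L > spec$box_index)
  vars <- unlist(ordering$boxes[later], use.names = FALSE)
  lapply(vars, function(v) term_spec("main", v))
}

drop_one <- function(terms, i) terms[-i]

protected_mains <- function(terms) {
  higher <- Filter(function(tm) tm$kind != "main", terms)
  unique(unlist(lapply(higher, `[[`, "variables")))
}

#' Select a node model by backward elimination with higher-order screening
#'
#' Starting from the full set of candidate main effects, the term with the
#' largest p-value is repeatedly dropped until all retained terms have
#' p < alpha. If enabled, pairwise products of the retained variables and
#' their squares are then screened one at a time: the most significant
#' augmentation (p < alpha) is added, the model re-pruned, and screening
#' repeats until no augmentation is significant. The procedure is
#' hierarchical: a main effect is never dropped while a retained interaction
#' or quadratic involves its variable. Exact p ties are broken by candidate
#' order.
#'
#' @param t A log-scale `cohort_table` (complete cases are taken over the
#'   response and all candidate variables).
#' @param response Response variable name.
#' @param candidates List of main-effect [term_spec()]s (e.g. from
#'   [candidate_terms()]).
#' @param cfg A [fit_config()].
#' @return A `node_model` with a `selection_log` attribute (data frame of
#'   steps) and a `centers` element recording the centering constants used.
#' @export
select_model <- function(t, response, candidates, cfg = fit_config()) {
  stopifnot(inherits(t, "cohort_table"), t$log_applied)
  cand_vars <- unique(unlist(lapply(candidates, `[[`, "variables")))
  tcc <- complete_cases(t, c(response, cand_vars))
  dat <- tcc$data
  n <- nrow(dat)
  log_steps <- list()
  note <- function(action, term, p)
    log_steps[[length(log_steps) + 1L]] <<-
      data.frame(action = action, term = term, p = p, stringsAsFactors = FALSE)

  current <- candidates
  if (n < length(current) + 3L) {
    keep_k <- max(0L, n - 3L)
    warning(sprintf("only %d rows for %d candidates in model for '%s'; starting from the first %d",
                    n, length(current), response, keep_k), call. = FALSE)
    current <- current[seq_len(keep_k)]
    note("reduce", "(starting set truncated)", NA_real_)
  }
  centers <- if (cfg$center_before_products)
    vapply(dat[cand_vars], mean, numeric(1)) else
    stats::setNames(rep(0, length(cand_vars)), cand_vars)

  refit <- function(terms) {
    X <- build_design(dat, terms, centers = centers)
    ols_engine(dat[[response]], X)
  }
  prune <- function(terms) {
    repeat {
      if (length(terms) == 0L) return(list(terms = terms, fit = refit(terms)))
      fitres <- refit(terms)
      pvals <- fitres$p[-1L]
      prot <- protected_mains(terms)
      droppable <- vapply(terms, function(tm)
        !(tm$kind == "main" && tm$variables %in% prot), logical(1))
      if (!any(droppable)) return(list(terms = terms, fit = fitres))
      pv <- ifelse(droppable, pvals, -Inf)
      worst <- which.max(pv)
      if (pv[worst] < cfg$alpha) return(list(terms = terms, fit = fitres))
      note("drop", term_label(terms[[worst]]), pvals[worst])
      terms <- drop_one(terms, worst)
    }
  }

  state <- prune(current)
  if (cfg$screen_interactions || cfg$screen_quadratics) {
    for (round in seq_len(25L)) {
      base_vars <- if (cfg$screen_scope == "retained") {
        unique(unlist(lapply(Filter(function(tm) tm$kind == "main", state$terms),
                             `[[`, "variables")))
      } else cand_vars
      base_vars <- base_vars[order(match(base_vars, cand_vars))]
      aug <- list()
      if (cfg$screen_interactions && length(base_vars) >= 2L) {
        prs <- utils::combn(base_vars, 2L, simplify = FALSE)
        aug <- c(aug, lapply(prs, function(p) term_spec("interaction", p)))
      }
      if (cfg$screen_quadratics && length(base_vars) >= 1L)
        aug <- c(aug, lapply(base_vars, function(v) term_spec("quadratic", v)))
      have <- terms_labels(state$terms)
      aug <- Filter(function(tm) !(term_label(tm) %in% have), aug)
      if (length(aug) == 0L) break
      pnew <- vapply(aug, function(tm) {
        trial <- c(state$terms, list(tm))
        fitres <- tryCatch(refit(trial), error = function(e) NULL)
        if (is.null(fitres)) return(Inf)
        fitres$p[length(trial) + 1L]
      }, numeric(1))
      best <- which.min(pnew)
      if (!is.finite(pnew[best]) || pnew[best] >= cfg$alpha) break
      added <- aug[[best]]
      note("add", term_label(added), pnew[best])
      # hierarchy: ensure main effects of the added term are present
      trial <- state$terms
      for (v in added$variables) {
        if (!any(vapply(trial, function(tm)
          tm$kind == "main" && identical(tm$variables, v), logical(1)))) {
          trial <- c(trial, list(term_spec("main", v)))
          note("add", v, NA_real_)
        }
      }
      trial <- c(trial, list(added))
      state <- prune(trial)
    }
  }
  mod <- make_node_model(response, state$terms, state$fit,
                         centers = centers[unique(unlist(lapply(state$terms, `[[`, "variables")))],
                         alpha = cfg$alpha)
  attr(mod, "selection_log") <-
    if (length(log_steps)) do.call(rbind, log_steps) else
      data.frame(action = character(0), term = character(0), p = numeric(0))
  mod
}
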