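#' Construct a linear-Gaussian system over a block ordering
#'
#' The system is the no-interaction linearization of a regression graph: in
#' a background-first topological order, each variable is a linear function
#' of earlier variables plus a Gaussian error; errors are correlated only
#' within boxes (block-diagonal error covariance).
#'
#' @param order Character vector of variable names, background first (i.e.
#'   decreasing box index); coefficients must respect this order.
#' @param coef_matrix Square matrix, `coef_matrix[response, explanatory]`;
#'   must be strictly lower-triangular in `order` and zero within boxes.
#' @param error_cov Symmetric positive-definite error covariance,
#'   block-diagonal by box.
#' @param box Named integer vector of box indices (used for validation and
#'   for mapping to/from graphs); optional.
#' @return An object of class `gaussian_system`.
#' @export
gaussian_system <- function(order, coef_matrix, error_cov, box = NULL) {
  p <- length(order)
  stopifnot(identical(dim(coef_matrix), c(p, p)),
            identical(dim(error_cov), c(p, p)))
  dimnames(coef_matrix) <- dimnames(error_cov) <- list(order, order)
  if (any(abs(coef_matrix[upper.tri(coef_matrix, diag = TRUE)]) > 0))
    stop("coef_matrix must be strictly lower-triangular in the given order",
         call. = FALSE)
  if (max(abs(error_cov - t(error_cov))) > 1e-12)
    stop("error_cov must be symmetric", call. = FALSE)
  ev <- eigen(error_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("error_cov must be positive definite", call. = FALSE)
  if (!is.null(box)) {
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      same_box <- box[[order[i]]] == box[[order[j]]]
      if (same_box && coef_matrix[i, j] != 0)
        stop("within-box coefficient not allowed: ", order[i], " ~ ", order[j],
             call. = FALSE)
      if (!same_box && error_cov[i, j] != 0)
        stop("cross-box error covariance not allowed: ", order[i], ", ",
             order[j], call. = FALSE)
    }
  }
  structure(list(order = order, coef_matrix = coef_matrix,
                 error_cov = error_cov, box = box),
            class = "gaussian_system")
}

#' Implied covariance of a linear-Gaussian system
#'
#' Solves the structural relations `y = coef %*% y + e` for the reduced form
#' `y = (I - coef)^{-1} e` and propagates the error covariance.
#'
#' @param sys A [gaussian_system()].
#' @return The symmetric positive-definite covariance matrix of the joint
#'   distribution, with variable names as dimnames.
#' @export
implied_covariance <- function(sys) {
  p <- length(sys$order)
  IB <- diag(p) - sys$coef_matrix
  # IB is lower-triangular with unit diagonal; Minv = IB^{-1}
  Minv <- forwardsolve(IB, diag(p))
  S <- Minv %*% sys$error_cov %*% t(Minv)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(sys$order, sys$order)
  S
}

#' Partial correlation from a covariance matrix
#'
#' Computed by inverting the covariance submatrix over `{x, y}` and the
#' conditioning set: with concentration matrix `K`, the partial correlation
#' is `-K[x,y] / sqrt(K[x,x] * K[y,y])`.
#'
#' @param cov Covariance matrix with dimnames.
#' @param x,y Variable names (not in `given`).
#' @param given Character vector of conditioning variables.
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(cov, x, y, given = character(0)) {
  vars <- c(x, y, given)
  if (x %in% given || y %in% given || x == y)
    stop("`x`, `y` must be distinct and outside `given`", call. = FALSE)
  sub <- cov[vars, vars, drop = FALSE]
  K <- tryCatch(solve(sub), error = function(e)
    stop("singular covariance submatrix in partial correlation", call. = FALSE))
  -K[x, y] / sqrt(K[x, x] * K[y, y])
}

#' Convert a regression graph with generic weights to a Gaussian system
#'
#' Every arrow receives the supplied (or randomly drawn) structural
#' coefficient; every dashed or full edge an error correlation; error
#' variances are 1.
#'
#' @param g A [regression_graph()].
#' @param coef_fun Function `(n)` drawing arrow coefficients.
#' @param corr_fun Function `(n)` drawing within-box error correlations.
#' @return A [gaussian_system()] whose nonzero structure mirrors `g` exactly.
#' @export
graph_to_system <- function(g,
                            coef_fun = function(n) stats::runif(n, 0.4, 1.2) *
                              sample(c(-1, 1), n, replace = TRUE),
                            corr_fun = function(n) stats::runif(n, 0.2, 0.45) *
                              sample(c(-1, 1), n, replace = TRUE)) {
  ord <- g$nodes[order(-g$box[g$nodes], match(g$nodes, g$nodes))]
  p <- length(ord)
  B <- matrix(0, p, p, dimnames = list(ord, ord))
  if (nrow(g$arrows)) {
    w <- coef_fun(nrow(g$arrows))
    for (i in seq_len(nrow(g$arrows)))
      B[g$arrows[i, 2L], g$arrows[i, 1L]] <- w[i]
  }
  # error covariance, box by box: dashed edges have covariance-graph
  # semantics (missing edge = zero error covariance), full lines have
  # concentration-graph semantics (missing edge = zero error partial
  # correlation given the rest of the context box)
  V <- matrix(0, p, p, dimnames = list(ord, ord))
  fill_block <- function(vars, edges, concentration) {
    m <- length(vars)
    M <- diag(m)
    dimnames(M) <- list(vars, vars)
    if (nrow(edges)) {
      r <- corr_fun(nrow(edges))
      for (i in seq_len(nrow(edges))) {
        M[edges[i, 1L], edges[i, 2L]] <- r[i]
        M[edges[i, 2L], edges[i, 1L]] <- r[i]
      }
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 1e-8) M <- M + diag(m) * (1e-6 + abs(min(ev)))
    }
    if (concentration) solve(M) else M
  }
  for (b in unique(g$box)) {
    vars <- g$nodes[g$box[g$nodes] == b]
    is_context <- g$kind[[vars[[1L]]]] == "context"
    edges <- if (is_context) g$full else g$dashed
    keep <- edges[, 1L] %in% vars & edges[, 2L] %in% vars
    V[vars, vars] <- fill_block(vars, edges[keep, , drop = FALSE], is_context)
  }
  gaussian_system(ord, B, V, box = g$box)
}

#' Check that graph separations imply vanishing partial correlations
#'
#' For every pair of distinct nodes and every conditioning set of size at
#' most `max_cond`, compares [m_separated()] on the graph with the partial
#' correlation implied by the Gaussian system. A separation with
#' `|partial correlation| >= tol` is a Markov violation (expected never); a
#' non-separation with `|partial correlation| < faithfulness_tol` is logged
#' as a faithfulness violation (possible only on measure-zero parameter
#' cancellations).
#'
#' @param g A [regression_graph()].
#' @param sys A [gaussian_system()] whose nonzero structure mirrors `g`.
#' @param max_cond Maximum conditioning-set size.
#' @param tol Threshold below which a partial correlation counts as zero.
#' @param faithfulness_tol Threshold for logging faithfulness violations.
#' @return List with `n_queries`, `markov_violations` (data frame),
#'   `faithfulness_violations` (data frame).
#' @export
check_markov_consistency <- function(g, sys, max_cond = 2L, tol = 1e-10,
                                     faithfulness_tol = 1e-6) {
  if (!setequal(g$nodes, sys$order))
    stop("graph and system are over different variables", call. = FALSE)
  # structure must mirror: every arrow a nonzero coefficient and vice versa
  B <- sys$coef_matrix
  arrow_keys <- if (nrow(g$arrows))
    paste(g$arrows[, 2L], g$arrows[, 1L]) else character(0)
  nz <- which(B != 0, arr.ind = TRUE)
  nz_keys <- paste(sys$order[nz[, 1L]], sys$order[nz[, 2L]])
  if (!setequal(arrow_keys, nz_keys))
    stop("system coefficients do not mirror the graph's arrows", call. = FALSE)
  S <- implied_covariance(sys)
  nodes <- sort(g$nodes)
  mk <- fv <- list()
  n_queries <- 0L
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    x <- nodes[i]; y <- nodes[j]
    rest <- sort(setdiff(nodes, c(x, y)))
    for (k in 0:min(max_cond, length(rest))) {
      sets <- if (k == 0L) list(character(0)) else
        utils::combn(rest, k, simplify = FALSE)
      for (C in sets) {
        n_queries <- n_queries + 1L
        sep <- m_separated(g, x, y, C)
        pc <- partial_correlation(S, x, y, C)
        if (sep && abs(pc) >= tol)
          mk[[length(mk) + 1L]] <- data.frame(
            x = x, y = y, given = paste(C, collapse = ","), pcor = pc)
        if (!sep && abs(pc) < faithfulness_tol)
          fv[[length(fv) + 1L]] <- data.frame(
            x = x, y = y, given = paste(C, collapse = ","), pcor = pc)
      }
    }
  }
  bind0 <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(x = character(0), y = character(0), given = character(0),
               pcor = numeric(0))
  list(n_queries = n_queries, markov_violations = bind0(mk),
       faithfulness_violations = bind0(fv))
}

#' Partition query: regression of one variable on others given a chosen set
#'
#' The data-level form of a global-Markov partition query: regress `y` on
#' `xs` together with the conditioning set `given` (all on the log scale)
#' and report inference for the `xs` coefficients only.
#'
#' @param t A log-scale `cohort_table`.
#' @param y Response name.
#' @param xs Character vector of variables of interest.
#' @param given Character vector of conditioning variables (may be empty).
#' @return A data frame with one row per `xs` entry: `term`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, plus attributes `n` and `r_squared`.
#' @export
partition_query <- function(t, y, xs, given = character(0)) {
  stopifnot(inherits(t, "cohort_table"), t$log_applied)
  vars <- unique(c(xs, given))
  tcc <- complete_cases(t, c(y, vars))
  terms <- lapply(vars, function(v) term_spec("main", v))
  X <- build_design(tcc$data, terms)
  fitres <- ols_engine(tcc$data[[y]], X)
  mod <- make_node_model(y, terms, fitres, centers = NULL)
  keep <- match(xs, terms_labels(mod$terms))
  out <- data.frame(term = xs, beta = mod$beta[keep], se = mod$se[keep],
                    ci_low = mod$ci_low[keep], ci_high = mod$ci_high[keep],
                    p = mod$p[keep], stringsAsFactors = FALSE)
  attr(out, "n") <- mod$n_used
  attr(out, "r_squared") <- mod$r_squared
  out
}
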