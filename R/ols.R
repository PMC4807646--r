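#' Term specification for a node model
#'
#' @param kind `"main"`, `"interaction"` or `"quadratic"`.
#' @param variables One variable name (main, quadratic) or two distinct names
#'   (interaction).
#' @param label Optional display label; defaults to `a`, `a:b` or `a^2`.
#' @return An object of class `term_spec`.
#' @export
term_spec <- function(kind = c("main", "interaction", "quadratic"),
                      variables, label = NULL) {
  kind <- match.arg(kind)
  variables <- as.character(variables)
  if (kind == "interaction") {
    if (length(variables) != 2L || variables[1L] == variables[2L])
      stop("interaction terms need exactly two distinct variables", call. = FALSE)
    variables <- sort(variables)
  } else if (length(variables) != 1L) {
    stop(kind, " terms need exactly one variable", call. = FALSE)
  }
  if (is.null(label))
    label <- switch(kind,
                    main = variables,
                    interaction = paste(variables, collapse = ":"),
                    quadratic = paste0(variables, "^2"))
  structure(list(kind = kind, variables = variables, label = label),
            class = "term_spec")
}

term_label <- function(tm) tm$label

terms_labels <- function(terms) vapply(terms, term_label, character(1))

#' Build a design matrix for a list of terms
#'
#' Main effects enter as the (log-scale) columns themselves. Interaction and
#' quadratic columns are formed from mean-centered columns when `centers` is
#' supplied, so that main-effect coefficients read as slopes at the mean of
#' the co-factor; the product-term coefficient itself is unaffected by
#' centering.
#'
#' @param data A data frame of log-scale columns.
#' @param terms List of [term_spec()] objects.
#' @param centers Named numeric vector of centering constants, or `NULL` to
#'   use the column means of `data` (computed over the supplied rows).
#' @return A numeric matrix with one labelled column per term, with the
#'   centers used stored in attribute `centers`.
#' @export
build_design <- function(data, terms, centers = NULL) {
  used <- unique(unlist(lapply(terms, `[[`, "variables")))
  if (is.null(centers)) {
    centers <- vapply(data[used], mean, numeric(1))
  } else {
    missing_c <- setdiff(used, names(centers))
    if (length(missing_c))
      centers <- c(centers, vapply(data[missing_c], mean, numeric(1)))
  }
  cols <- lapply(terms, function(tm) {
    v <- tm$variables
    switch(tm$kind,
           main = data[[v]],
           interaction = (data[[v[1L]]] - centers[[v[1L]]]) *
                         (data[[v[2L]]] - centers[[v[2L]]]),
           quadratic = (data[[v]] - centers[[v]])^2)
  })
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(data), ncol = 0L)
  colnames(X) <- terms_labels(terms)
  attr(X, "centers") <- centers[used]
  X
}

ols_engine <- function(y, X) {
  # X: design WITHOUT intercept; intercept prepended here.
  n <- length(y)
  Xi <- cbind(`(intercept)` = rep(1, n), X)
  k <- ncol(Xi)
  if (n <= k)
    stop(sprintf("too few rows (%d) for %d coefficients", n, k), call. = FALSE)
  qd <- qr(Xi)
  if (qd$rank < k) {
    dep <- colnames(Xi)[qd$pivot[(qd$rank + 1L):k]]
    stop("collinear design; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qd, y)
  fitted <- drop(Xi %*% coef)
  res <- y - fitted
  df <- n - k
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qd))[order(qd$pivot), order(qd$pivot), drop = FALSE]
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  tval <- ifelse(se > 0, coef / se, 0)
  p <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(coef = coef, se = se, t = tval, p = p, df = df,
       sigma = sqrt(sigma2), r_squared = r2, residuals = res, n = n)
}

make_node_model <- function(response, terms, fitres, centers, alpha = 0.05) {
  tcrit <- stats::qt(0.975, fitres$df)
  idx <- seq_along(terms) + 1L  # skip intercept
  structure(
    list(response = response,
         terms = terms,
         beta = unname(fitres$coef[idx]),
         se = unname(fitres$se[idx]),
         ci_low = unname(fitres$coef[idx] - tcrit * fitres$se[idx]),
         ci_high = unname(fitres$coef[idx] + tcrit * fitres$se[idx]),
         p = unname(fitres$p[idx]),
         intercept = unname(fitres$coef[1L]),
         r_squared = fitres$r_squared,
         sigma = fitres$sigma,
         n_used = fitres$n,
         df = fitres$df,
         centers = centers,
         alpha = alpha),
    class = "node_model")
}

#' Ordinary least squares with t-based inference
#'
#' Fits a single response by least squares and returns the partial regression
#' coefficients with two-sided p-values and 95% confidence intervals from the
#' t distribution on the residual degrees of freedom.
#'
#' @param y Numeric response vector.
#' @param design Numeric matrix with labelled columns (no intercept column;
#'   an intercept is always included), or a data frame.
#' @param terms Optional list of [term_spec()] describing the columns; by
#'   default each column is treated as a main effect named after its label.
#' @param response Name recorded for the response (default `"y"`).
#' @return A `node_model` with elements `terms`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `p`, `intercept`, `r_squared`, `sigma`, `n_used`.
#' @export
fit_ols <- function(y, design, terms = NULL, response = "y") {
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(terms))
    terms <- lapply(colnames(X), function(nm) term_spec("main", nm, label = nm))
  keep <- stats::complete.cases(cbind(y, X))
  fitres <- ols_engine(y[keep], X[keep, , drop = FALSE])
  make_node_model(response, terms, fitres, centers = NULL)
}

#' @export
print.node_model <- function(x, ...) {
  cat(sprintf("Node model for '%s' (n = %d, R^2 = %.3f, sigma = %.4f)\n",
              x$response, x$n_used, x$r_squared, x$sigma))
  if (length(x$terms) == 0L) {
    cat("  (intercept-only model)\n")
    return(invisible(x))
  }
  df <- data.frame(term = terms_labels(x$terms),
                   beta = signif(x$beta, 3),
                   ci_low = signif(x$ci_low, 3),
                   ci_high = signif(x$ci_high, 3),
                   p = signif(x$p, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Interpret a log-log coefficient as a percent change
#'
#' On the log-log scale a partial regression coefficient is an elasticity: a
#' `pct`% difference in the regressor corresponds to approximately
#' `beta * pct`% difference in the outcome. The exact multiplicative reading
#' is `(1 + pct/100)^beta - 1`.
#'
#' @param beta Log-log partial regression coefficient.
#' @param pct Percent difference in the explanatory variable.
#' @return List with `linear_pct` (`beta * pct`) and `exact_pct`
#'   (`100 * ((1 + pct/100)^beta - 1)`).
#' @export
interpret_coefficient <- function(beta, pct) {
  list(linear_pct = beta * pct,
       exact_pct = 100 * ((1 + pct / 100)^beta - 1))
}

#' Turning point of a quadratic association on the log scale
#'
#' For a fitted response surface `beta1 * z + beta2 * z^2` in a log-scale
#' regressor `z`, the vertex sits at `z = -beta1 / (2 * beta2)`; its
#' exponential is the original-scale location. `beta2 > 0` flags a minimum
#' (U-shape), `beta2 < 0` a maximum.
#'
#' @param beta1 Linear coefficient.
#' @param beta2 Quadratic coefficient (non-zero).
#' @return List with `log_location`, `location` (original scale) and `type`
#'   (`"minimum"`/`"maximum"`).
#' @export
quadratic_turning_point <- function(beta1, beta2) {
  if (beta2 == 0) stop("no vertex: quadratic coefficient is zero", call. = FALSE)
  v <- -beta1 / (2 * beta2)
  list(log_location = v, location = exp(v),
       type = if (beta2 > 0) "minimum" else "maximum")
}
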