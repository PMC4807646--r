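test_that("OLS fits reproduce closed-form and normal-equation results", {
  x <- 1:5
  mod <- fit_ols(x, cbind(x = x))
  expect_equal(mod$beta, 1)
  expect_equal(mod$r_squared, 1)
  expect_equal(mod$sigma, 0)

  y <- c(2, 1, 4, 3, 6)
  mod <- fit_ols(y, cbind(x = x))
  expect_equal(mod$beta, 1.0, tolerance = 1e-12)
  expect_equal(mod$intercept, 0.2, tolerance = 1e-12)

  set.seed(8)
  for (i in 1:20) {
    n <- sample(20:60, 1); k <- sample(1:5, 1)
    X <- matrix(stats::rnorm(n * k), n)
    colnames(X) <- paste0("x", seq_len(k))
    yy <- stats::rnorm(n)
    mod <- fit_ols(yy, X)
    Xi <- cbind(1, X)
    ref <- drop(solve(t(Xi) %*% Xi, t(Xi) %*% yy))
    expect_equal(c(mod$intercept, mod$beta), unname(ref), tolerance = 1e-10)
    # matches stats::lm inference
    lmfit <- summary(stats::lm(yy ~ X))
    expect_equal(mod$p, unname(lmfit$coefficients[-1, 4]), tolerance = 1e-10)
    expect_equal(mod$r_squared, lmfit$r.squared, tolerance = 1e-12)
  }

  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(stats::rnorm(10), X), "collinear.*b")
})

test_that("candidate terms come from strictly later boxes in order", {
  ord <- default_ordering()
  cand <- candidate_terms("csa_dis", ord)
  expect_equal(vapply(cand, function(tm) tm$label, ""),
               c("lean_mass", "fat_mass_pct", "height", "adiponectin",
                 "leptin", "osteocalcin", "ucoc", "phylloquinone", "age"))
  expect_equal(vapply(candidate_terms("leptin", ord), function(tm) tm$label, ""),
               "age")
  fm <- vapply(candidate_terms("fat_mass_pct", ord), function(tm) tm$label, "")
  expect_false(any(c("csa_dis", "lean_mass") %in% fm))
  expect_true(all(c("leptin", "adiponectin", "age") %in% fm))
  expect_error(candidate_terms("age", ord), "context")
})

test_that("backward elimination keeps strong signals and drops noise", {
  ord <- block_ordering(list(
    list(variable_spec("y", 0, "response")),
    lapply(paste0("x", 1:4), function(nm) variable_spec(nm, 0, "response"))),
    c("response", "response"))
  set.seed(11)
  n <- 500
  dat <- as.data.frame(lapply(stats::setNames(paste0("x", 1:4), paste0("x", 1:4)),
                              function(nm) exp(stats::rnorm(n, 0, 0.4))))
  dat$y <- exp(0.8 * log(dat$x1) + stats::rnorm(n, 0, 0.3))
  tab <- log_transform_cohort(cohort_table(dat, ord))
  mod <- select_model(tab, "y", candidate_terms("y", ord),
                      fit_config(screen_interactions = FALSE,
                                 screen_quadratics = FALSE))
  expect_equal(vapply(mod$terms, function(tm) tm$label, ""), "x1")
  expect_equal(mod$beta, 0.8, tolerance = 0.1)
  expect_s3_class(attr(mod, "selection_log"), "data.frame")
})

test_that("pure-noise candidates are retained at about the nominal rate", {
  ord <- block_ordering(list(
    list(variable_spec("y", 0, "response")),
    lapply(paste0("x", 1:6), function(nm) variable_spec(nm, 0, "response"))),
    c("response", "response"))
  cfg <- fit_config(screen_interactions = FALSE, screen_quadratics = FALSE)
  cand <- candidate_terms("y", ord)
  set.seed(220)
  kept <- 0L; total <- 0L
  for (i in 1:400) {
    dat <- as.data.frame(matrix(exp(stats::rnorm(70 * 7, 0, 0.3)), 70,
                                dimnames = list(NULL, c("y", paste0("x", 1:6)))))
    tab <- log_transform_cohort(cohort_table(dat, ord))
    mod <- select_model(tab, "y", cand, cfg)
    kept <- kept + length(mod$terms)
    total <- total + 6L
  }
  expect_gt(kept / total, 0.03)
  expect_lt(kept / total, 0.08)
})

test_that("interaction screening is hierarchical", {
  ord <- block_ordering(list(
    list(variable_spec("y", 0, "response")),
    lapply(paste0("x", 1:3), function(nm) variable_spec(nm, 0, "response"))),
    c("response", "response"))
  set.seed(14)
  n <- 300
  x1 <- stats::rnorm(n, 0, 0.5); x2 <- stats::rnorm(n, 0, 0.5)
  x3 <- stats::rnorm(n, 0, 0.5)
  y <- 0.9 * (x1 - mean(x1)) * (x2 - mean(x2)) + stats::rnorm(n, 0, 0.3)
  dat <- data.frame(y = exp(y), x1 = exp(x1), x2 = exp(x2), x3 = exp(x3))
  tab <- log_transform_cohort(cohort_table(dat, ord))
  mod <- select_model(tab, "y", candidate_terms("y", ord),
                      fit_config(screen_scope = "all"))
  labs <- vapply(mod$terms, function(tm) tm$label, "")
  expect_true("x1:x2" %in% labs)
  expect_true(all(c("x1", "x2") %in% labs))  # mains kept under hierarchy
  hit <- match("x1:x2", labs)
  expect_equal(mod$beta[hit], 0.9, tolerance = 0.15)
})

test_that("rescaling a variable changes no slope, p-value or R-squared", {
  spec <- default_spec_cached()
  co <- simulate_cohort(spec, 70, seed = 77)
  ord <- spec$ordering
  cfg <- fit_config()
  fit1 <- select_model(log_transform_cohort(co), "csa_dis",
                       candidate_terms("csa_dis", ord), cfg)
  co2 <- co
  co2$data$lean_mass <- co2$data$lean_mass * 1000   # kg -> g
  co2$data$adiponectin <- co2$data$adiponectin / 1000
  fit2 <- select_model(log_transform_cohort(co2), "csa_dis",
                       candidate_terms("csa_dis", ord), cfg)
  expect_equal(vapply(fit1$terms, function(tm) tm$label, ""),
               vapply(fit2$terms, function(tm) tm$label, ""))
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit1$p, fit2$p, tolerance = 1e-10)
  expect_equal(fit1$r_squared, fit2$r_squared, tolerance = 1e-10)
})

test_that("within-box tests control size and detect correlated errors", {
  ord <- block_ordering(list(
    list(variable_spec("a", 0, "response"), variable_spec("b", 0, "response")),
    list(variable_spec("x", 0, "response"))), c("response", "response"))
  set.seed(55)
  rej <- 0L
  for (i in 1:300) {
    x <- stats::rnorm(70, 0, 0.5)
    dat <- data.frame(a = exp(0.5 * x + stats::rnorm(70, 0, 0.3)),
                      b = exp(-0.4 * x + stats::rnorm(70, 0, 0.3)),
                      x = exp(x))
    tab <- log_transform_cohort(cohort_table(dat, ord))
    res <- within_box_test(tab, "a", "b", "x")
    if (res$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 300, 0.02)
  expect_lt(rej / 300, 0.09)

  det <- 0L
  for (i in 1:50) {
    x <- stats::rnorm(70, 0, 0.5)
    E <- matrix(stats::rnorm(140), 70) %*% chol(matrix(c(1, .5, .5, 1), 2)) * 0.3
    dat <- data.frame(a = exp(0.5 * x + E[, 1]), b = exp(-0.4 * x + E[, 2]),
                      x = exp(x))
    tab <- log_transform_cohort(cohort_table(dat, ord))
    if (within_box_test(tab, "a", "b", "x")$p < 0.05) det <- det + 1L
  }
  expect_gt(det / 50, 0.8)

  tab <- log_transform_cohort(cohort_table(
    data.frame(a = exp(stats::rnorm(20)), b = exp(stats::rnorm(20)),
               x = exp(stats::rnorm(20))), ord))
  expect_error(within_box_test(tab, "a", "a", "x"), "differ")
})

test_that("log-log coefficients translate to percent differences", {
  ic <- interpret_coefficient(-0.06, 10)
  expect_equal(ic$linear_pct, -0.6)
  expect_equal(ic$exact_pct, 100 * (1.1^-0.06 - 1), tolerance = 1e-12)
  expect_equal(interpret_coefficient(1, 7.3)$linear_pct, 7.3)
})

test_that("quadratic turning points locate the vertex on both scales", {
  tp <- quadratic_turning_point(-1.1, 0.2)
  expect_equal(tp$log_location, 2.75)
  expect_equal(tp$type, "minimum")
  # grid-search oracle on the original scale
  grid <- seq(5, 50, by = 0.001)
  val <- -1.1 * log(grid) + 0.2 * log(grid)^2
  expect_equal(tp$location, grid[which.min(val)], tolerance = 1e-2)
  expect_equal(quadratic_turning_point(0, 0.3)$log_location, 0)
  expect_equal(quadratic_turning_point(1, -2)$type, "maximum")
  expect_error(quadratic_turning_point(1, 0), "vertex")
})

test_that("full-model confidence intervals cover the generative coefficients", {
  spec <- default_spec_cached()
  rec <- recovery_experiment(spec, n = 70, reps = 400, seed = 900,
                             select = FALSE, responses = "csa_dis")
  expect_true(all(rec$retention_rate == 1))
  # binomial tolerance around 0.95 at 400 replicates
  expect_true(all(rec$coverage > 0.91 & rec$coverage < 0.985))
})
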