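test_that("the default spec is valid and carries the published term sets", {
  spec <- default_spec_cached()
  expect_length(validate_spec(spec), 0)
  expect_true(spec$calibrated)

  labs <- function(resp) vapply(spec$equations[[resp]]$terms,
                                function(tm) tm$label, "")
  expect_setequal(labs("csa_dis"),
                  c("lean_mass", "height", "adiponectin", "ucoc",
                    "adiponectin:ucoc"))
  expect_setequal(labs("vbmd_tot_dis"),
                  c("adiponectin", "phylloquinone", "phylloquinone^2"))
  expect_setequal(labs("cort_vbmd_dia"), c("lean_mass", "osteocalcin"))
  cdia <- spec$equations$csa_dia
  expect_true("adiponectin:age" %in% labs("csa_dia"))
  # product and square coefficients are parameterization-invariant
  co <- function(resp, lab) {
    eqv <- spec$equations[[resp]]
    eqv$coef[match(lab, vapply(eqv$terms, function(tm) tm$label, ""))]
  }
  expect_equal(co("csa_dis", "adiponectin:ucoc"), -0.10)
  expect_equal(co("csa_dia", "adiponectin:age"), -1.2)
  expect_equal(co("cort_area_dia", "age:phylloquinone"), 0.64)
  expect_equal(co("csa_dia", "osteocalcin^2"), 0.2)
  expect_equal(co("vbmd_tot_dis", "phylloquinone^2"), 0.03)
  expect_equal(co("csa_dis", "lean_mass"), 0.46)
  expect_equal(co("csa_dis", "height"), 0.92)
  expect_equal(co("fat_mass_pct", "leptin"), 0.32)
  expect_equal(co("lean_mass", "osteocalcin"), -0.07)
  expect_equal(co("csa_dia", "leptin"), -0.06)

  # linearized copy converts losslessly to a Gaussian system
  sys <- spec_to_gaussian_system(spec)
  expect_s3_class(sys, "gaussian_system")
  expect_equal(sys$coef_matrix["fat_mass_pct", "leptin"], 0.32)
  expect_equal(sys$coef_matrix["csa_dis", "lean_mass"], 0.46)
})

test_that("simulation is deterministic given spec and seed", {
  spec <- default_spec_cached()
  a <- simulate_cohort(spec, 50, seed = 123)
  b <- simulate_cohort(spec, 50, seed = 123)
  expect_identical(a$data, b$data)
  c <- simulate_cohort(spec, 50, seed = 124)
  expect_false(identical(a$data, c$data))
})

test_that("a noiseless response returns its coefficients exactly", {
  # zeroing a response's own error (its regressors stay stochastic) makes
  # the refit exact with R^2 = 1; zeroing every SD would degenerate the
  # design itself (e.g. FM percentage becomes an exact function of leptin)
  spec <- default_spec_cached()
  spec$equations$csa_dia$error_sd <- 1e-10
  tl <- log_transform_cohort(simulate_cohort(spec, 400, seed = 9))
  eqv <- spec$equations$csa_dia
  tcc <- complete_cases(tl, c("csa_dia",
                              unique(unlist(lapply(eqv$terms, `[[`, "variables")))))
  X <- build_design(tcc$data, eqv$terms,
                    centers = seqregraph:::spec_centers(spec))
  fit <- fit_ols(tcc$data$csa_dia, X, terms = eqv$terms, response = "csa_dia")
  expect_equal(fit$beta, eqv$coef, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-12)
})

test_that("simulated marginals track the published summary statistics", {
  spec <- default_spec_cached()
  d <- descriptives(simulate_cohort(spec, 5000, seed = 71))
  tab1 <- list(
    age = c(62.3, 3.7), adiponectin = c(9.4, 3.5), leptin = c(18.5, 15.2),
    osteocalcin = c(21.2, 7.8), ucoc = c(7.4, 6.9), phylloquinone = c(0.8, 0.7))
  for (nm in names(tab1)) {
    row <- d[d$variable == nm, ]
    se_mean <- row$sd / sqrt(row$n)
    expect_lt(abs(row$mean - tab1[[nm]][1]), 3 * se_mean)
    se_sd <- row$sd / sqrt(2 * (row$n - 1))
    expect_lt(abs(row$sd - tab1[[nm]][2]), 4 * se_sd + 0.05 * tab1[[nm]][2])
  }
  # truncation at the published range
  expect_gte(d$min[d$variable == "age"], 55.5)
  expect_lte(d$max[d$variable == "age"], 70.9)
  # response means and the distal CSA dispersion
  tgt <- c(csa_dis = 1110, csa_dia = 376, lean_mass = 47.6, fat_mass_pct = 29.2)
  for (nm in names(tgt)) {
    row <- d[d$variable == nm, ]
    expect_lt(abs(row$mean - tgt[[nm]]) / tgt[[nm]], 0.02)
  }
  expect_lt(abs(d$sd[d$variable == "csa_dis"] - 121) / 121, 0.10)
})

test_that("noise calibration hits and orders the R-squared targets", {
  spec <- default_spec_cached()
  # monotone: a larger target demands a smaller error SD
  r2a <- spec$r2_targets; r2a["csa_dis"] <- 0.3
  r2b <- spec$r2_targets; r2b["csa_dis"] <- 0.6
  sa <- calibrate_noise(spec, r2a, n = 20000, seed = 5)
  sb <- calibrate_noise(spec, r2b, n = 20000, seed = 5)
  expect_gt(sa$equations$csa_dis$error_sd, sb$equations$csa_dis$error_sd)

  # near-1 target drives the error SD toward zero
  r2c <- spec$r2_targets; r2c["fat_mass_pct"] <- 0.999
  sc <- calibrate_noise(spec, r2c, n = 20000, seed = 5)
  expect_lt(sc$equations$fat_mass_pct$error_sd,
            spec$equations$fat_mass_pct$error_sd / 10)

  # refit at large n recovers the target
  tl <- log_transform_cohort(simulate_cohort(spec, 40000, seed = 6))
  eqv <- spec$equations$fat_mass_pct
  X <- build_design(tl$data, eqv$terms)
  fit <- fit_ols(tl$data$fat_mass_pct, X)
  expect_equal(fit$r_squared, 0.71, tolerance = 0.015)
})

test_that("MCAR missingness is injected at the requested rate", {
  spec <- default_spec_cached()
  spec$missing_rate <- 0.1
  co <- simulate_cohort(spec, 2000, seed = 13)
  miss <- vapply(co$data, function(v) mean(is.na(v)), numeric(1))
  expect_true(all(abs(miss - 0.1) < 0.03))
  cc <- complete_cases(co, c("csa_dis", "lean_mass"))
  expect_lt(nrow(cc$data), nrow(co$data))
})

test_that("recovery experiments aggregate bias, coverage and retention", {
  spec <- default_spec_cached()
  rec <- recovery_experiment(spec, n = 2000, reps = 5, seed = 17,
                             select = FALSE,
                             responses = c("fat_mass_pct", "lean_mass"))
  expect_setequal(rec$term, c("leptin", "osteocalcin"))
  expect_true(all(rec$retention_rate == 1))
  expect_lt(max(abs(rec$bias)), 0.02)
  est <- attr(rec, "estimates")
  expect_equal(dim(est), c(5L, 2L))

  # with selection, estimates are recorded only where retained
  rec2 <- recovery_experiment(spec, n = 70, reps = 5, seed = 18,
                              responses = "fat_mass_pct")
  lep <- rec2[rec2$term == "leptin", ]
  expect_equal(lep$retention_rate, 1)  # t ~ 13, always retained
  expect_equal(lep$mean_estimate, 0.32, tolerance = 0.1)
})
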