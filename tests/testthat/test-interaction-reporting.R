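test_that("tertile grids hold geometric means of manually partitioned cells", {
  ord <- block_ordering(list(
    list(variable_spec("out", 0, "response")),
    list(variable_spec("f1", 0, "response"), variable_spec("f2", 0, "response"))),
    c("response", "response"))
  set.seed(90)
  n <- 120
  dat <- data.frame(out = stats::rlnorm(n, 3, 0.4),
                    f1 = stats::rlnorm(n, 1, 0.5),
                    f2 = stats::rlnorm(n, 2, 0.5))
  tab <- cohort_table(dat, ord)
  g <- tertile_grid(tab, "out", "f1", "f2")
  expect_equal(sum(g$counts), n)

  s1 <- tertile_split(dat$f1); s2 <- tertile_split(dat$f2)
  for (i in c("low", "mid", "high")) for (j in c("low", "mid", "high")) {
    sel <- which(s1$labels == i & s2$labels == j)
    if (length(sel))
      expect_equal(g$cells[i, j], geometric_mean(dat$out[sel]),
                   tolerance = 1e-12)
  }

  # constant outcome: every non-empty cell equals the constant
  dat$out <- rep(11, n)
  gc <- tertile_grid(cohort_table(dat, ord), "out", "f1", "f2")
  expect_equal(gc$cells[gc$counts > 0],
               rep(11, sum(gc$counts > 0)), tolerance = 1e-12)

  expect_error(tertile_grid(log_transform_cohort(tab), "out", "f1", "f2"),
               "original scale")
})

test_that("grid contrasts are exact percent ratios", {
  g <- structure(list(cells = matrix(c(100, 90, NA, 100, 100, 100, 100, 100, 100),
                                     3, dimnames = list(c("low", "mid", "high"),
                                                        c("low", "mid", "high")))),
                 class = "tertile_grid")
  expect_equal(grid_contrast(g, c("low", "low"), c("low", "mid")), 0)
  expect_equal(grid_contrast(g, c("mid", "low"), c("low", "low")), -10)
  expect_error(grid_contrast(g, c("high", "low"), c("low", "low")),
               "empty")
})

test_that("the age-adiponectin interaction shows in the tertile grid", {
  spec <- default_spec_cached()
  co <- simulate_cohort(spec, 3000, seed = 33)
  g <- tertile_grid(co, "csa_dia", "adiponectin", "age")
  # negative product term: among high-adiponectin women, the oldest tertile
  # has smaller diaphyseal CSA than the youngest
  expect_lt(g$cells["high", "high"], g$cells["high", "low"])
  contrast <- grid_contrast(g, c("high", "high"), c("high", "low"))
  expect_lt(contrast, 0)
})

test_that("the pipeline runs end-to-end, deterministically, on file inputs", {
  spec <- default_spec_cached()
  csv <- write_temp_cohort(spec, 150, seed = 61)
  out1 <- file.path(tempfile(), "r1")
  out2 <- file.path(tempfile(), "r2")
  rep1 <- run_pipeline(csv, tibia_config_path(), alpha = 0.05, out_dir = out1)
  rep2 <- run_pipeline(csv, tibia_config_path(), alpha = 0.05, out_dir = out2)

  expect_s3_class(rep1, "pipeline_report")
  expect_setequal(names(rep1$fit$models),
                  c(spec$ordering$boxes[[1]], spec$ordering$boxes[[2]],
                    spec$ordering$boxes[[3]]))
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_true(file.exists(file.path(out1, "graph.dot")))
  expect_true(file.exists(file.path(out1, "models.tsv")))

  # determinism: byte-identical reports
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))

  # DOT output parses back to the fitted graph
  edges <- parse_dot_edges(paste(readLines(file.path(out1, "graph.dot")),
                                 collapse = "\n"))
  expect_setequal(paste(edges$arrows[, 1], edges$arrows[, 2]),
                  paste(rep1$fit$graph$arrows[, 1], rep1$fit$graph$arrows[, 2]))

  # an automatic grid exists for every retained interaction
  n_int <- sum(vapply(rep1$fit$models, function(m)
    sum(vapply(m$terms, function(tm) tm$kind == "interaction", logical(1))),
    numeric(1)))
  expect_gte(length(rep1$grids), n_int)

  # partition queries ride along
  rep3 <- run_pipeline(csv, tibia_config_path(),
                       queries = list(list(y = "lean_mass", xs = "ucoc",
                                           given = "osteocalcin")))
  expect_equal(rep3$queries[[1]]$table$term, "ucoc")
})

test_that("formatted coefficient tables mirror the node models", {
  spec <- default_spec_cached()
  co <- simulate_cohort(spec, 150, seed = 62)
  fit <- fit_sequence(co, spec$ordering)
  tab <- coefficient_table(fit, responses = c("csa_dis", "fat_mass_pct"))
  expect_equal(names(tab), c("term", "csa_dis", "fat_mass_pct"))
  expect_equal(tab$term[nrow(tab)], "R^2")
  mod <- fit$models$fat_mass_pct
  i <- match("leptin", vapply(mod$terms, function(tm) tm$label, ""))
  if (!is.na(i)) {
    want <- sprintf("%s (%s, %s)", signif(mod$beta[i], 2),
                    signif(mod$ci_low[i], 2), signif(mod$ci_high[i], 2))
    expect_equal(tab$fat_mass_pct[match("leptin", tab$term)], want)
  }
  expect_equal(tab$fat_mass_pct[nrow(tab)],
               as.character(signif(mod$r_squared, 2)))
})
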