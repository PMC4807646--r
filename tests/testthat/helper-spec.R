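# The calibrated default generator is moderately expensive to build; share
# one instance across test files.
default_spec_cached <- local({
  spec <- NULL
  function() {
    if (is.null(spec)) spec <<- default_spec()
    spec
  }
})

# interaction-free copy: keep only main-effect terms so that simulated data
# follow the linear-Gaussian oracle exactly
strip_interactions <- function(spec) {
  for (nm in names(spec$equations)) {
    eqv <- spec$equations[[nm]]
    keep <- vapply(eqv$terms, function(tm) tm$kind == "main", logical(1))
    eqv$terms <- eqv$terms[keep]
    eqv$coef <- eqv$coef[keep]
    spec$equations[[nm]] <- eqv
  }
  spec
}

write_temp_cohort <- function(spec, n, seed) {
  co <- simulate_cohort(spec, n, seed = seed)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(co$data, path, row.names = FALSE)
  path
}

tibia_config_path <- function() {
  system.file("extdata", "tibia-ordering.yaml", package = "seqregraph")
}
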