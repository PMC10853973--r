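# Shared small synthetic cohort, built once per test run.
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function(n = 80, seed = 42) {
  key <- paste0("c", n, "_", seed)
  if (is.null(.cohort_cache[[key]])) {
    sim <- synthetic_cohort(n = n, seed = seed)
    sim$table <- aggregate_best_per_run(sim$records)
    sim$curves <- build_curves(sim$table)
    .cohort_cache[[key]] <- sim
  }
  .cohort_cache[[key]]
}

# A clean synthetic score curve straight from the Gaussian model.
gaussian_curve <- function(mu, sigma = 18, amp = 100, mz = 1200,
                           grid = sweep_grid(), noise_sd = 0,
                           cal = ce_calibration()) {
  x <- applied_ce(mz, as.numeric(grid), cal)
  keep <- !duplicated(x)
  x <- x[keep]
  y <- amp * exp(-(x - mu)^2 / (2 * sigma^2))
  if (noise_sd > 0) y <- y * (1 + stats::rnorm(length(x), 0, noise_sd))
  list(ce = x, score = pmax(y, 0), scale_pct = as.numeric(grid)[keep],
       grid = grid, channel = "byonic")
}
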