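test_that("species sampling is deterministic, diverse and tryptic", {
  a <- sample_species(10, seed = 7)
  b <- sample_species(10, seed = 7)
  expect_identical(vapply(a, species_key, character(1)),
                   vapply(b, species_key, character(1)))
  expect_identical(a[[3]]$retention_time, b[[3]]$retention_time)
  one <- sample_species(1, seed = 3)
  expect_s3_class(one[[1]], "glycopeptide_species")
  # coverage: charge x sialylation strata all populated at default n
  sim <- small_cohort(n = 200, seed = 1)
  ft <- sim$features
  strata <- table(ft$charge >= 3, ft$n_sialic > 0)
  expect_true(all(strata > 0))
  # tryptic C-terminus, no internal K/R
  seqs <- vapply(sim$species, function(s) s$sequence, character(1))
  expect_true(all(grepl("[KR]$", seqs)))
  expect_false(any(grepl("[KR].", seqs)))
})

test_that("true optima follow the persona's linear model with sign contracts", {
  sim <- small_cohort()
  ft <- sim$features
  # degenerate persona: no covariates, no noise -> exact line
  p0 <- persona_params("peptide_centric", coef_hydrophobicity = 0,
                       coef_mobile_protons = 0, coef_glycan_mass = 0,
                       optimum_noise_sd = 0)
  mu <- true_optimum(ft, p0)
  expect_equal(mu, pmin(200, pmax(5, p0$intercept + p0$slope_mz * ft$mz)))
  # one extra mobile proton with a negative coefficient lowers the optimum
  ft2 <- ft[1, , drop = FALSE]
  ft2$mobile_protons <- ft2$mobile_protons + 1
  p1 <- persona_params("glycan_centric", optimum_noise_sd = 0)
  expect_lt(true_optimum(ft2, p1), true_optimum(ft[1, , drop = FALSE], p1))
  # glycan-centric optima sit at about half the peptide-centric energy
  pep <- persona_params("peptide_centric", optimum_noise_sd = 0)
  gly <- persona_params("glycan_centric", optimum_noise_sd = 0)
  means <- ft[1, , drop = FALSE]
  for (v in c("hydrophobicity", "mobile_protons", "glycan_mass"))
    means[[v]] <- mean(ft[[v]])
  for (mz in c(700, 1200, 1800)) {
    means$mz <- mz
    ratio <- true_optimum(means, gly) / true_optimum(means, pep)
    expect_gt(ratio, 0.4)
    expect_lt(ratio, 0.6)
  }
  expect_error(persona_params("peptide_centric", no_such = 1), "unknown")
})

test_that("sweep simulation honors noise, threshold and duplicate contracts", {
  sp <- sample_species(12, seed = 4)
  quiet <- channel_personas(
    peptide = list(multiplicative_score_noise_sd = 0, optimum_noise_sd = 0,
                   detection_threshold = 0),
    glycan = list(multiplicative_score_noise_sd = 0, optimum_noise_sd = 0,
                  detection_threshold = 0))
  sim <- simulate_sweep(sp, personas = quiet, seed = 2, p_dup = 0)
  # noiseless, threshold 0: every species present at every setting
  counts <- table(sim$records$channel)
  expect_true(all(counts == 12 * 28))
  # scores are exactly Gaussian in the applied energy
  r1 <- sim$records[sim$records$channel == "byonic" &
                      sim$records$sequence == sp[[1]]$sequence &
                      sim$records$glycan_composition ==
                        format_glycan_composition(sp[[1]]$glycan), ]
  tr <- sim$truth[sim$truth$species_key == species_key(sp[[1]]) &
                    sim$truth$channel == "byonic", ]
  ce <- applied_ce(theoretical_mz(sp[[1]]), r1$scale_pct)
  expect_equal(r1$score,
               tr$true_amplitude * exp(-(ce - tr$true_mu)^2 /
                                         (2 * tr$true_sigma^2)),
               tolerance = 1e-9)
  # a threshold above every peak score silences the sweep
  mute <- channel_personas(peptide = list(detection_threshold = 1e9),
                           glycan = list(detection_threshold = 1e9))
  sim2 <- simulate_sweep(sp, personas = mute, seed = 2, p_dup = 0)
  expect_equal(nrow(sim2$records), 0L)
  # missingness grows monotonically with the detection threshold
  n_at <- vapply(c(0, 20, 200, 2000), function(thr) {
    pers <- channel_personas(peptide = list(detection_threshold = thr),
                             glycan = list(detection_threshold = thr))
    nrow(simulate_sweep(sp, personas = pers, seed = 2, p_dup = 0)$records)
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
  # duplicates appear and are removed by per-run aggregation
  sim3 <- simulate_sweep(sp, personas = quiet, seed = 2, p_dup = 0.3)
  expect_gt(nrow(sim3$records), nrow(sim$records))
  expect_equal(nrow(aggregate_best_per_run(sim3$records)),
               nrow(sim$records))
})

test_that("emitted report files are per-setting, complete and reproducible", {
  sp <- sample_species(6, seed = 8)
  sim <- simulate_sweep(sp, seed = 3)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  emit_reports(sim$records, dir1)
  expect_length(list.files(dir1, pattern = "^run_.*\\.tsv$"), 28)
  expect_true(file.exists(file.path(dir1, "manifest.tsv")))
  # settings without identifications still produce a header-only file
  first <- read_report(file.path(dir1, "run_006.25pct.tsv"), "normalized")
  expect_s3_class(first, "data.frame")
  # byte-identical re-emission under the same seed
  sim_b <- simulate_sweep(sample_species(6, seed = 8), seed = 3)
  emit_reports(sim_b$records, dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(sort(f1))),
                   unname(tools::md5sum(sort(f2))))
})

test_that("the full pipeline recovers persona coefficients from reports", {
  sim <- small_cohort(n = 200, seed = 1)
  opt <- fit_optima(sim$curves)
  ft <- sim$features
  d <- opt[opt$channel == "glycoquest", ]
  fd <- ft[match(d$species_key, ft$species_key), ]
  fit <- lm(d$optimal_ce_ev ~ fd$mz + fd$hydrophobicity +
              fd$mobile_protons + fd$glycan_mass)
  p <- sim$personas$glycoquest
  est <- coef(fit)
  expect_equal(unname(est[2]), p$slope_mz, tolerance = 0.15)
  expect_equal(unname(est[4]), p$coef_mobile_protons, tolerance = 0.15)
  expect_equal(unname(est[5]), p$coef_glycan_mass, tolerance = 0.3)
})
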