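test_that("trendline reproduces exact lines and recovers generator slopes", {
  mz <- seq(700, 1900, length.out = 40)
  ce <- 0.0607 * mz + 13.57
  tl <- suppressWarnings(fit_trendline(mz, ce, "byonic"))
  expect_equal(tl$slope, 0.0607, tolerance = 1e-10)
  expect_equal(tl$intercept, 13.57, tolerance = 1e-7)
  expect_equal(tl$r_squared, 1)
  # two distinct duplicated points define the line through them
  tl2 <- suppressWarnings(
    fit_trendline(c(800, 800, 1600, 1600), c(60, 60, 110, 110)))
  expect_equal(tl2$slope, 50 / 800)
  expect_error(fit_trendline(rep(1000, 5), rnorm(5)), "degenerate")
  expect_error(fit_trendline(c(1, 2), c(1, 2)), "3 points")
  # parameter recovery on a synthetic peptide-centric cohort
  sim <- small_cohort(n = 200, seed = 1)
  opt <- fit_optima(sim$curves)
  d <- opt[opt$channel == "pglyco_peptide", ]
  persona <- sim$personas$pglyco_peptide
  # regress out the covariate terms so the m/z slope is isolated
  ftd <- sim$features[match(d$species_key, sim$features$species_key), ]
  partial <- d$optimal_ce_ev -
    persona$coef_hydrophobicity * ftd$hydrophobicity -
    persona$coef_mobile_protons * ftd$mobile_protons
  tl3 <- fit_trendline(d$mz, partial, "pglyco_peptide")
  expect_equal(tl3$slope, persona$slope_mz, tolerance = 0.1)
})

test_that("slope homogeneity test calibrates under the null and detects unequal slopes", {
  set.seed(99)
  n <- 60
  mz <- runif(n, 700, 1900)
  grp <- factor(rep(c("a", "b"), each = n / 2))
  # null: identical slopes -> moderate number of rejections
  p_null <- vapply(1:120, function(i) {
    y <- 10 + 0.06 * mz + 3 * (grp == "b") + rnorm(n, 0, 2)
    test_slope_homogeneity(y, mz, grp)$p
  }, numeric(1))
  rate <- mean(p_null < 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.15)
  # strong interaction: slope differs between groups
  p_alt <- vapply(1:40, function(i) {
    y <- 10 + (0.06 + 0.02 * (grp == "b")) * mz + rnorm(n, 0, 2)
    test_slope_homogeneity(y, mz, grp)$p
  }, numeric(1))
  expect_gt(mean(p_alt < 0.05), 0.9)
  # single populated level errors; rare levels are merged
  expect_error(test_slope_homogeneity(rnorm(10), runif(10),
                                      factor(rep("a", 10))), "2 populated")
  expect_warning(
    test_slope_homogeneity(rnorm(20), runif(20),
                           factor(c(rep("a", 10), rep("b", 9), "c"))),
    "merged")
})

test_that("ancova reports exact nulls and per-level contrasts against the reference", {
  set.seed(5)
  mz <- runif(80, 700, 1900)
  cov <- rnorm(80)
  # response exactly linear in mz: covariate coefficient 0, p ~ 1
  y <- 5 + 0.05 * mz
  a <- suppressWarnings(ancova(y, mz, cov))
  expect_lt(abs(a$coefficients[["variable"]]), 1e-9)
  expect_gt(a$covariate_p, 0.99)
  # categorical contrasts vs the stated reference level
  grp <- factor(sample(0:2, 80, replace = TRUE))
  y2 <- 5 + 0.05 * mz - 4 * (grp == "1") - 8 * (grp == "2") +
    rnorm(80, 0, 1)
  a2 <- ancova(y2, mz, grp, reference_level = "0")
  expect_equal(a2$reference_level, "0")
  expect_setequal(a2$contrasts$level, c("1", "2"))
  expect_equal(a2$contrasts$estimate[a2$contrasts$level == "2"], -8,
               tolerance = 0.5)
  expect_true(all(a2$contrasts$p_value < 0.01))
  # trendline and ancova coincide when the extra variable is constant
  expect_error(ancova(y2, mz, rep(1.5, 80)), "degenerate")
})

test_that("ancova hydrophobicity p-values are uniform under a true null", {
  sim <- small_cohort()
  ft <- sim$features
  n <- nrow(ft)
  ps <- vapply(1:300, function(s) {
    set.seed(7000 + s)
    y <- 10 + 0.06 * ft$mz + rnorm(n, 0, 3)
    ancova(y, ft$mz, ft$hydrophobicity)$covariate_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("lasso path hits its closed-form limits", {
  set.seed(21)
  n <- 120
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 + 1.5 * X$a - 0.8 * X$b + rnorm(n, 0, 0.5)
  path <- lasso_path(X, y, thresh = 1e-12)
  # above the deactivation threshold every slope is exactly zero
  expect_true(all(abs(path$beta[, 1]) == 0))
  # the small-penalty end approaches ordinary least squares
  ols <- coef(lm(y ~ ., data = X))
  expect_equal(unname(path$beta[, ncol(path$beta)]), unname(ols[-1]),
               tolerance = 1e-3)
  # active-set size is non-increasing as the penalty grows
  sizes <- colSums(abs(path$beta) > 0)
  expect_true(all(diff(sizes) >= 0))  # lambda stored decreasing
  # constant features are dropped with a warning
  X$flat <- 1
  expect_warning(lasso_path(X, y), "constant")
})

test_that("select_features applies the delta-R2 rule and is monotone in delta", {
  set.seed(31)
  n <- 150
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- 1 + 2 * X$x1 + 1.5 * X$x2 - X$x3 + 0.8 * X$x4 + rnorm(n, 0, 0.7)
  path <- lasso_path(X, y)
  sel <- select_features(path, delta_r2 = 0.01)
  expect_setequal(as.character(sel), c("x1", "x2", "x3", "x4"))
  # delta 0 returns a set refitting to the full-model R2
  sel0 <- select_features(path, delta_r2 = 0)
  expect_gte(attr(sel0, "r_squared"), attr(sel0, "full_r_squared") - 1e-12)
  # monotone: larger tolerance never selects a larger set
  deltas <- c(0, 0.005, 0.01, 0.05, 0.2)
  sizes <- vapply(deltas, function(d)
    length(select_features(path, d)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # pure-noise response collapses to (nearly) nothing; n large enough
  # that overfitting R2 (~p/n) sits below the selection tolerance
  set.seed(32)
  Xn <- as.data.frame(matrix(rnorm(2000 * 6), ncol = 6))
  ynoise <- rnorm(2000)
  seln <- select_features(lasso_path(Xn, ynoise), 0.01)
  expect_lte(length(seln), 1)
  expect_lt(attr(seln, "r_squared"), 0.1)
})

test_that("selection finds an information-equivalent set on glycopeptide features", {
  # On real glycopeptide feature matrices the true generating set is not
  # identifiable: derived features (peptide-only m/z, masses) are exact or
  # near rotations of {mz, hydrophobicity, charge, glycan mass}. What must
  # hold is that the selected set explains the response as well as the
  # true set does.
  sim <- small_cohort(n = 200, seed = 1)
  X <- sim$features[, setdiff(names(sim$features), "species_key")]
  truth <- c("mz", "hydrophobicity", "charge", "glycan_mass")
  ok <- 0L
  for (s in 1:10) {
    set.seed(5000 + s)
    y <- 10 + 0.0607 * X$mz + 0.6 * X$hydrophobicity + 6 * X$charge -
      0.006 * X$glycan_mass + rnorm(nrow(X), 0, 3)
    sel <- select_features(suppressWarnings(lasso_path(X, y)), 0.01)
    r2_true <- summary(lm(y ~ ., data = X[, truth]))$r.squared
    if (attr(sel, "r_squared") >= r2_true - 0.01 &&
        length(sel) <= length(truth)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("pearson guards degenerate input and matches known cases", {
  x <- rnorm(20)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(x, rep(1, 20)), "zero variance")
  expect_error(pearson(1:2, 2:3), "n >= 3")
  # charge and mobile protons are strongly correlated on the default cohort
  sim <- small_cohort(n = 200, seed = 1)
  r <- pearson(sim$features$charge, sim$features$mobile_protons)
  expect_gt(r, 0.5)
  expect_lt(r, 0.9)
})

test_that("model_report summarizes every channel", {
  sim <- small_cohort()
  opt <- fit_optima(sim$curves)
  rep <- suppressWarnings(model_report(opt, sim$features))
  expect_true(all(vapply(rep, function(r)
    is.finite(r$trendline$slope), logical(1))))
  expect_true(all(c("byonic", "glycoquest") %in% names(rep)))
  expect_true(all(vapply(rep, function(r)
    r$lasso$full_r_squared >= r$lasso$selected_r_squared - 1e-9,
    logical(1))))
})
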