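# Statistical analysis of fitted optima: per-channel linear CE-vs-m/z
# trendlines, ANCOVA-style general linear models with a homogeneity-of-
# slopes gate, an L1-regularization path with empirical minimal-feature
# selection, and correlation diagnostics.

#' Linear CE-vs-m/z trendline
#'
#' Ordinary least squares of optimal CE on precursor m/z — the global
#' trend every score channel follows.
#'
#' @param mz Precursor m/z values (Th).
#' @param ce Optimal CE values (eV).
#' @param channel Optional channel label carried into the result.
#' @return A `trendline_fit`: `channel`, `slope` (eV/Th), `intercept`
#'   (eV), `r_squared`, `n`.
#' @export
fit_trendline <- function(mz, ce, channel = NA_character_) {
  stopifnot(length(mz) == length(ce))
  if (length(mz) < 3L) stop("trendline requires at least 3 points")
  if (stats::sd(mz) < .Machine$double.eps^0.5)
    stop("degenerate m/z variance")
  fit <- stats::lm(ce ~ mz)
  structure(list(channel = channel,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = length(mz)),
            class = "trendline_fit")
}

#' @export
print.trendline_fit <- function(x, ...) {
  cat(sprintf("<trendline %s> CE = %.4f * m/z + %.2f  (R2 = %.3f, n = %d)\n",
              x$channel, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

# Merge factor levels with < 2 observations into "other", with a warning.
merge_rare_levels <- function(f, min_n = 2L) {
  f <- factor(f)
  tab <- table(f)
  rare <- names(tab)[tab < min_n]
  if (length(rare)) {
    warning("factor level(s) with < ", min_n, " observations merged into ",
            dQuote("other"), ": ", paste(rare, collapse = ", "),
            call. = FALSE)
    levels(f)[levels(f) %in% rare] <- "other"
  }
  droplevels(f)
}

#' Homogeneity-of-slopes test
#'
#' F-test of the model with an m/z-by-variable interaction against the
#' additive model: do subgroups (or a continuous covariate) change the
#' slope of the CE-vs-m/z dependence, or only its level? Factor levels
#' with fewer than two observations are merged into `"other"` with a
#' warning.
#'
#' @param ce Optimal CE values (response).
#' @param mz Precursor m/z values.
#' @param variable Grouping factor or continuous covariate.
#' @return List: `F`, `p`, `df` (interaction and residual degrees of
#'   freedom), `variable_type`.
#' @export
test_slope_homogeneity <- function(ce, mz, variable) {
  stopifnot(length(ce) == length(mz), length(ce) == length(variable))
  is_factor <- is.factor(variable) || is.character(variable) ||
    is.logical(variable)
  if (is_factor) {
    variable <- merge_rare_levels(variable)
    if (nlevels(variable) < 2L)
      stop("homogeneity test needs at least 2 populated factor levels")
  } else if (stats::sd(variable) < .Machine$double.eps^0.5) {
    stop("degenerate continuous covariate")
  }
  additive <- stats::lm(ce ~ mz + variable)
  interact <- stats::lm(ce ~ mz * variable)
  cmp <- stats::anova(additive, interact)
  list(F = cmp$F[2], p = cmp$`Pr(>F)`[2],
       df = c(cmp$Df[2], cmp$Res.Df[2]),
       variable_type = if (is_factor) "categorical" else "continuous")
}

#' ANCOVA-style general linear model for one structural variable
#'
#' Tests whether a structural variable carries information about the
#' optimal CE beyond m/z. The homogeneity-of-slopes test decides the model
#' form: the m/z-by-variable interaction is retained iff its p-value is
#' below `alpha` (default 0.05). For categorical variables (charge, mobile
#' protons, sialic acid count) each level is contrasted against
#' `reference_level` with two-sided p-values; for continuous variables
#' (hydrophobicity) the covariate's partial test is reported.
#'
#' @param ce,mz Response and m/z covariate.
#' @param variable Structural variable (factor or numeric).
#' @param reference_level Reference level for categorical contrasts (e.g.
#'   `"0"` for zero mobile protons). Defaults to the first level.
#' @param alpha Homogeneity gate level.
#' @return A `glm_result`: model description, interaction F/p, covariate
#'   p (continuous), per-level contrast table (categorical), coefficients.
#' @export
ancova <- function(ce, mz, variable, reference_level = NULL, alpha = 0.05) {
  hom <- test_slope_homogeneity(ce, mz, variable)
  categorical <- hom$variable_type == "categorical"
  if (categorical) {
    variable <- merge_rare_levels(variable)
    if (!is.null(reference_level)) {
      if (!reference_level %in% levels(variable))
        stop("reference level ", dQuote(reference_level),
             " not present in the variable")
      variable <- stats::relevel(variable, ref = as.character(reference_level))
    }
  }
  use_interaction <- is.finite(hom$p) && hom$p < alpha
  form <- if (use_interaction) ce ~ mz * variable else ce ~ mz + variable
  fit <- stats::lm(form)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  smry <- summary(fit)$coefficients
  contrasts <- NULL
  covariate_p <- NA_real_
  if (categorical) {
    rows <- grep("^variable", rownames(smry), value = TRUE)
    rows <- rows[!grepl(":", rows)]
    contrasts <- data.frame(
      level = sub("^variable", "", rows),
      estimate = smry[rows, "Estimate"],
      p_value = smry[rows, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    # type-II convention: the covariate's significance besides m/z is its
    # partial F-test in the additive model, independent of the gate
    # decision. An exactly-fitting m/z-only model (zero residual sum of
    # squares to machine precision) makes the F ratio 0/0; that degenerate
    # null is reported as p = 1.
    base_fit <- stats::lm(ce ~ mz)
    add_fit <- stats::lm(ce ~ mz + variable)
    tss <- sum((ce - mean(ce))^2)
    ss_cov <- sum(base_fit$residuals^2) - sum(add_fit$residuals^2)
    covariate_p <- if (ss_cov <= 1e-12 * tss &&
                       sum(add_fit$residuals^2) <= 1e-12 * tss) 1
    else stats::anova(base_fit, add_fit)$`Pr(>F)`[2]
  }
  structure(list(
    formula = paste(deparse(form), collapse = ""),
    model = if (use_interaction) "interaction" else "additive",
    interaction_F = hom$F, interaction_p = hom$p,
    covariate_p = covariate_p,
    reference_level = if (categorical) levels(variable)[1] else NA_character_,
    contrasts = contrasts,
    coefficients = stats::coef(fit)),
    class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<GLM %s model> interaction p = %.3g\n", x$model,
              x$interaction_p))
  if (!is.null(x$contrasts)) {
    cat("contrasts vs reference ", dQuote(x$reference_level), ":\n", sep = "")
    print(x$contrasts)
  } else {
    cat(sprintf("covariate p = %.3g\n", x$covariate_p))
  }
  invisible(x)
}

#' L1-regularization path for optimal CE
#'
#' Lasso regression of the optimal CE on a candidate feature matrix,
#' solved over a logarithmic penalty grid running from the all-zero
#' deactivation threshold `max |X's y_c| / n` (standardized features,
#' centered response) down four decades. Features are standardized before
#' penalization; coefficients are reported on the original scale. Constant
#' features are dropped with a warning. The solver is coordinate descent
#' (glmnet).
#'
#' @param features Numeric matrix or data frame of candidate covariates.
#' @param ce Response (optimal CE, eV).
#' @param n_lambda Number of penalty values.
#' @param decades How many decades below the deactivation threshold to
#'   probe.
#' @param thresh Coordinate-descent convergence tolerance.
#' @return A `lasso_path` object: `lambda`, `beta` (features x penalties,
#'   original scale), `intercept`, `r_squared` per penalty, `features`
#'   (names), plus the training `x`/`y` for refitting.
#' @export
lasso_path <- function(features, ce, n_lambda = 100, decades = 4,
                       thresh = 1e-7) {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(ce))
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[sds < .Machine$double.eps^0.5],
                  collapse = ", "), call. = FALSE)
    x <- x[, sds >= .Machine$double.eps^0.5, drop = FALSE]
  }
  if (nrow(x) <= ncol(x))
    warning("fewer observations than candidate features; ",
            "selection will be unstable", call. = FALSE)
  n <- nrow(x)
  # population-sd standardization to match the coordinate-descent solver's
  # internal scaling, so the path's top penalty is the exact deactivation
  # threshold max |x_j' y_c| / n
  xs <- scale(x, scale = sqrt(colMeans(scale(x, scale = FALSE)^2)))
  lambda_max <- max(abs(crossprod(xs, ce - mean(ce)))) / n
  lambda <- 10^seq(log10(lambda_max), log10(lambda_max) - decades,
                   length.out = n_lambda)
  fit <- glmnet::glmnet(x, ce, alpha = 1, lambda = lambda,
                        standardize = TRUE, thresh = thresh)
  beta <- as.matrix(fit$beta)
  structure(list(lambda = fit$lambda, beta = beta,
                 intercept = as.numeric(fit$a0),
                 r_squared = fit$dev.ratio,
                 features = rownames(beta),
                 x = x, y = ce),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso path> %d penalties over %d features, final R2 = %.3f\n",
              length(x$lambda), length(x$features),
              x$r_squared[length(x$r_squared)]))
  invisible(x)
}

# Unpenalized R-squared of an OLS refit on a feature subset.
refit_r2 <- function(x, y, active) {
  if (!length(active)) return(0)
  fit <- stats::lm.fit(cbind(1, x[, active, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Empirical minimal feature set along the lasso path
#'
#' Scans the active sets along the regularization path and returns the
#' smallest one whose unpenalized (OLS-refit) R-squared is within
#' `delta_r2` of the full-model R-squared — the empirical "minimum set of
#' parameters above which no significant increase of R2 is observable".
#' Ties in size are resolved toward the larger penalty (sparser solution
#' reached first).
#'
#' @param path A [lasso_path()].
#' @param delta_r2 Allowed R-squared shortfall versus the full model.
#' @return Character vector of selected feature names, with attributes
#'   `"r_squared"` (of the refit) and `"full_r_squared"`.
#' @export
select_features <- function(path, delta_r2 = 0.01) {
  stopifnot(inherits(path, "lasso_path"))
  if (!length(path$lambda)) stop("empty regularization path")
  full_r2 <- refit_r2(path$x, path$y, path$features)
  sets <- lapply(seq_along(path$lambda), function(j)
    path$features[abs(path$beta[, j]) > 0])
  sets <- c(list(character(0)), sets)  # the empty set is always a candidate
  keys <- vapply(sets, paste, character(1), collapse = "|")
  sets <- sets[!duplicated(keys)]
  sizes <- lengths(sets)
  for (size in sort(unique(sizes))) {
    for (idx in which(sizes == size)) {
      r2 <- refit_r2(path$x, path$y, sets[[idx]])
      if (r2 >= full_r2 - delta_r2)
        return(structure(sets[[idx]], r_squared = r2,
                         full_r_squared = full_r2))
    }
  }
  structure(path$features, r_squared = full_r2, full_r_squared = full_r2)
}

#' Pearson correlation with degeneracy guards
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("Pearson correlation requires n >= 3")
  if (stats::sd(x) < .Machine$double.eps^0.5 ||
      stats::sd(y) < .Machine$double.eps^0.5)
    stop("zero variance input")
  stats::cor(x, y)
}

#' Per-channel model report
#'
#' Convenience wrapper producing the full statistical summary for a table
#' of optima joined to features: the CE-vs-m/z trendline per channel, GLM
#' tables for hydrophobicity (continuous), mobile protons and sialic acid
#' count (categorical), the lasso path summary with selected features, and
#' the charge/mobile-proton correlation.
#'
#' @param optima Data frame from [fit_optima()].
#' @param features Data frame from [feature_table()] (matched on
#'   `species_key`).
#' @param delta_r2 Feature-selection tolerance.
#' @param alpha Homogeneity-of-slopes gate level.
#' @return Nested list (one element per channel) suitable for JSON export.
#' @export
model_report <- function(optima, features, delta_r2 = 0.01, alpha = 0.05) {
  stopifnot(nrow(optima) > 0)
  merged <- merge(optima[, c("species_key", "channel", "optimal_ce_ev")],
                  features, by = "species_key")
  lasso_cols <- setdiff(names(features), "species_key")
  out <- lapply(split(merged, merged$channel), function(d) {
    tl <- fit_trendline(d$mz, d$optimal_ce_ev, d$channel[1])
    glms <- list()
    if (stats::sd(d$hydrophobicity) > 1e-8)
      glms$hydrophobicity <- ancova(d$optimal_ce_ev, d$mz,
                                    d$hydrophobicity, alpha = alpha)
    for (v in c("mobile_protons", "n_sialic")) {
      f <- factor(d[[v]])
      if (nlevels(suppressWarnings(merge_rare_levels(f))) >= 2L) {
        # small cohorts can produce aliased interaction designs; such
        # variables are skipped rather than failing the whole report
        g <- tryCatch(suppressWarnings(
          ancova(d$optimal_ce_ev, d$mz, f,
                 reference_level = if ("0" %in% levels(f)) "0" else NULL,
                 alpha = alpha)), error = function(e) NULL)
        if (!is.null(g)) glms[[v]] <- g
      }
    }
    path <- suppressWarnings(
      lasso_path(d[, lasso_cols[lasso_cols %in% names(d)]],
                 d$optimal_ce_ev))
    sel <- select_features(path, delta_r2)
    list(channel = d$channel[1],
         n = nrow(d),
         trendline = unclass(tl),
         glm = lapply(glms, unclass),
         lasso = list(selected_features = as.character(sel),
                      selected_r_squared = attr(sel, "r_squared"),
                      full_r_squared = attr(sel, "full_r_squared")),
         charge_mobile_proton_pearson =
           if (stats::sd(d$charge) > 1e-8 && stats::sd(d$mobile_protons) > 1e-8)
             pearson(d$charge, d$mobile_protons) else NA_real_)
  })
  out
}
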