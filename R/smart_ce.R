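# Smart collision-energy selection: how much identification score is
# gained by predicting the per-precursor CE from several online-available
# covariates instead of m/z alone. Scores at the predicted energies are
# read off the measured score-vs-CE curves (nearest measured setting), so
# the gain estimate needs no new measurements.

SMART_COVARIATES <- c("mz", "total_mass", "glycan_mass", "peptide_only_mz",
                      "hydrophobicity")

#' Fit a CE predictor
#'
#' Ordinary least squares of fitted optimal CE on either m/z alone (the
#' classical instrument rule) or the multivariate smart set: m/z, total
#' mass, glycan mass, peptide-only m/z and hydrophobicity — all
#' quantities obtainable online from MS1, retention time and a scout MS2.
#'
#' @param optima Data frame from [fit_optima()], one channel.
#' @param features Data frame from [feature_table()].
#' @param kind `"mz_only"` or `"multivariate"`.
#' @param channel Score channel to train on; default: the single channel
#'   present in `optima`.
#' @return A `ce_predictor` with `kind`, `channel`, `covariates`,
#'   `coefficients`.
#' @export
fit_predictor <- function(optima, features,
                          kind = c("mz_only", "multivariate"),
                          channel = NULL) {
  kind <- match.arg(kind)
  if (is.null(channel)) {
    channel <- unique(optima$channel)
    if (length(channel) != 1L)
      stop("multiple channels present; specify `channel`")
  }
  d <- merge(optima[optima$channel == channel,
                    c("species_key", "optimal_ce_ev")],
             features, by = "species_key")
  if (nrow(d) < 10L)
    stop("predictor training requires at least 10 species (got ",
         nrow(d), ")")
  covs <- if (kind == "mz_only") "mz" else SMART_COVARIATES
  X <- cbind(`(Intercept)` = 1, as.matrix(d[, covs, drop = FALSE]))
  fit <- stats::lm.fit(X, d$optimal_ce_ev)
  if (fit$rank < ncol(X))
    stop("rank-deficient design for the ", kind, " predictor")
  structure(list(kind = kind, channel = channel, covariates = covs,
                 coefficients = stats::coef(fit)),
            class = "ce_predictor")
}

#' @export
print.ce_predictor <- function(x, ...) {
  cat(sprintf("<CE predictor> %s [%s]\n", x$kind, x$channel))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Predict a collision energy
#'
#' Linear prediction, clipped to the instrument's energy floor and
#' ceiling.
#'
#' @param pred A `ce_predictor`.
#' @param features One feature row: named numeric vector, one-row data
#'   frame, or a matrix/data frame (vectorized over rows).
#' @param cal A [ce_calibration()] providing floor and ceiling.
#' @return Predicted energy in eV.
#' @export
predict_ce <- function(pred, features, cal = ce_calibration()) {
  stopifnot(inherits(pred, "ce_predictor"))
  if (is.null(dim(features)))
    features <- as.data.frame(as.list(features))
  missing <- setdiff(pred$covariates, colnames(features))
  if (length(missing))
    stop("missing covariate(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(features[, pred$covariates, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite covariate value")
  e <- drop(cbind(1, X) %*% pred$coefficients)
  unname(pmin(cal$ceiling, pmax(cal$floor, e)))
}

#' Score at the measured CE nearest a desired energy
#'
#' The practical surrogate for "what score would this species get at the
#' predicted CE": the score actually measured at the sweep setting whose
#' applied energy is closest to the desired one. Ties go to the lower
#' energy.
#'
#' @param curve A `score_curve`.
#' @param desired_ce Desired energy in eV.
#' @return Measured score.
#' @export
nearest_measured_score <- function(curve, desired_ce) {
  if (!length(curve$ce)) stop("empty score curve")
  curve$score[which.min(abs(curve$ce - desired_ce))]
}

#' Evaluate the smart-CE score gain
#'
#' For each species on one score channel, compares the score obtainable at
#' the m/z-only predicted CE (baseline) with the score at the multivariate
#' smart prediction, both read from the measured curve via
#' [nearest_measured_score()]. Reports per-species gain fractions, the
#' mean gain over all species, and the mean gain over the bottom fifth of
#' species ranked by baseline score (ties assigned to the bottom group).
#' Mode `"loo"` (default) refits both predictors without the evaluated
#' species; `"insample"` trains on all species.
#'
#' @param curves List of `score_curve` objects (any mix of channels).
#' @param optima Data frame from [fit_optima()].
#' @param features Data frame from [feature_table()].
#' @param channel Score channel to evaluate.
#' @param mode `"loo"` or `"insample"`.
#' @param cal A [ce_calibration()].
#' @return A `gain_report`: `channel`, `mode`, `n`, `mean_gain_pct`,
#'   `bottom_quintile_mean_gain_pct`, `per_species` data frame.
#' @export
evaluate_gain <- function(curves, optima, features, channel,
                          mode = c("loo", "insample"),
                          cal = ce_calibration()) {
  mode <- match.arg(mode)
  stopifnot(channel %in% SCORE_CHANNELS)
  opt <- optima[optima$channel == channel, , drop = FALSE]
  if (nrow(opt) < 10L)
    stop("gain evaluation requires at least 10 species with fitted optima")
  curve_map <- curves[vapply(curves, function(cu)
    cu$channel == channel, logical(1))]
  names(curve_map) <- vapply(curve_map, function(cu)
    species_key(cu$species), character(1))
  feat <- features[match(opt$species_key, features$species_key), ,
                   drop = FALSE]
  if (anyNA(feat$species_key))
    stop("features missing for some species with fitted optima")

  predict_pair <- function(train_idx, eval_row) {
    base <- fit_predictor(opt[train_idx, , drop = FALSE],
                          feat[train_idx, , drop = FALSE],
                          "mz_only", channel)
    smart <- fit_predictor(opt[train_idx, , drop = FALSE],
                           feat[train_idx, , drop = FALSE],
                           "multivariate", channel)
    c(base = predict_ce(base, feat[eval_row, , drop = FALSE], cal),
      smart = predict_ce(smart, feat[eval_row, , drop = FALSE], cal))
  }

  n <- nrow(opt)
  rows <- vector("list", n)
  if (mode == "insample") {
    base <- fit_predictor(opt, feat, "mz_only", channel)
    smart <- fit_predictor(opt, feat, "multivariate", channel)
    pred <- cbind(base = predict_ce(base, feat, cal),
                  smart = predict_ce(smart, feat, cal))
  } else {
    for (i in seq_len(n)) rows[[i]] <- predict_pair(setdiff(seq_len(n), i), i)
    pred <- do.call(rbind, rows)
  }
  per <- data.frame(species_key = opt$species_key,
                    baseline_ce = pred[, "base"],
                    smart_ce = pred[, "smart"],
                    baseline_score = NA_real_, smart_score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cu <- curve_map[[opt$species_key[i]]]
    if (is.null(cu)) next
    per$baseline_score[i] <- nearest_measured_score(cu, per$baseline_ce[i])
    per$smart_score[i] <- nearest_measured_score(cu, per$smart_ce[i])
  }
  ok <- is.finite(per$baseline_score) & per$baseline_score > 0 &
    is.finite(per$smart_score)
  if (!all(ok))
    warning(sum(!ok), " species dropped from the gain report ",
            "(no curve or non-positive baseline score)", call. = FALSE)
  per <- per[ok, , drop = FALSE]
  per$gain_fraction <- (per$smart_score - per$baseline_score) /
    per$baseline_score
  q20 <- stats::quantile(per$baseline_score, 0.2, names = FALSE)
  bottom <- per$baseline_score <= q20
  structure(list(channel = channel, mode = mode, n = nrow(per),
                 mean_gain_pct = 100 * mean(per$gain_fraction),
                 bottom_quintile_mean_gain_pct =
                   100 * mean(per$gain_fraction[bottom]),
                 per_species = per),
            class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf("<gain report> %s (%s, n = %d)\n", x$channel, x$mode, x$n))
  cat(sprintf("  mean gain:            %+.1f%%\n", x$mean_gain_pct))
  cat(sprintf("  bottom-quintile gain: %+.1f%%\n",
              x$bottom_quintile_mean_gain_pct))
  invisible(x)
}
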