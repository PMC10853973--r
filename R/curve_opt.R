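# Score-vs-CE curve construction, eligibility filtering, and optimal-CE
# extraction as the center of a fitted Gaussian. The nonlinear fit is a
# damped (Levenberg-Marquardt) least-squares solver written here because
# the Gaussian-center extraction is the core of the method; tests check it
# against general-purpose optimizers.

#' Eligibility policy for energy-dependent analysis
#'
#' A species/channel curve enters the optimal-CE analysis only if it was
#' identified confidently: its best score must exceed the channel's
#' acceptance threshold, it must be identified above threshold at a minimum
#' number of consecutive sweep settings, and carry a minimum number of
#' points overall. Default thresholds follow the usual acceptance scores
#' (Byonic > 300, pGlyco total > 15, GlycoQuest > 30); the pGlyco
#' sub-scores have no published threshold and default to 0 (presence
#' suffices).
#'
#' @param min_score Named numeric vector of per-channel score thresholds.
#' @param min_consecutive Minimum run of adjacent grid settings with
#'   above-threshold identifications.
#' @param min_points Minimum number of curve points.
#' @return An `eligibility_policy` object.
#' @export
eligibility_policy <- function(min_score = c(byonic = 300,
                                             pglyco_peptide = 0,
                                             pglyco_glycan = 0,
                                             pglyco_total = 15,
                                             glycoquest = 30),
                               min_consecutive = 4, min_points = 5) {
  stopifnot(all(SCORE_CHANNELS %in% names(min_score)),
            min_consecutive >= 1, min_points >= 1)
  structure(list(min_score = min_score, min_consecutive = min_consecutive,
                 min_points = min_points), class = "eligibility_policy")
}

#' Build per-species score-vs-CE curves
#'
#' Joins a deduplicated score table to the energy axis: each record's sweep
#' setting is converted to the energy actually applied at the species'
#' theoretical m/z via [applied_ce()]. One curve is produced per (species,
#' channel). Settings that saturate at the instrument ceiling map to the
#' same energy; such duplicate energies are collapsed to their best score
#' so curve energies are strictly increasing.
#'
#' @param table A `score_table` from [aggregate_best_per_run()].
#' @param cal A [ce_calibration()].
#' @param grid A [sweep_grid()]; every record's `scale_pct` must be on it.
#' @return List of `score_curve` objects, each with fields `species`,
#'   `channel`, `ce` (eV), `score`, `scale_pct`, `grid`.
#' @export
build_curves <- function(table, cal = ce_calibration(), grid = sweep_grid()) {
  stopifnot(nrow(table) > 0)
  on_grid <- vapply(table$scale_pct, function(s)
    any(abs(s - as.numeric(grid)) < 1e-9), logical(1))
  if (any(!on_grid))
    stop("record scale_pct not on the sweep grid: ",
         paste(unique(table$scale_pct[!on_grid]), collapse = ", "))
  key <- paste(table$sequence, table$glycan_composition, table$charge,
               table$channel, sep = "|")
  curves <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    rows <- table[idx, , drop = FALSE]
    sp <- try(glycopeptide_species(rows$sequence[1],
                                   rows$glycan_composition[1],
                                   rows$charge[1]), silent = TRUE)
    if (inherits(sp, "try-error")) {
      warning("skipping species with uncomputable m/z: ", rows$sequence[1],
              call. = FALSE)
      return(NULL)
    }
    mz <- theoretical_mz(sp)
    ce <- applied_ce(mz, rows$scale_pct, cal)
    ord <- order(ce, -rows$score)
    keep <- ord[!duplicated(ce[ord])]
    keep <- keep[order(ce[keep])]
    structure(list(species = sp, channel = rows$channel[1], mz = mz,
                   ce = ce[keep], score = rows$score[keep],
                   scale_pct = rows$scale_pct[keep], grid = grid),
              class = "score_curve")
  })
  curves[!vapply(curves, is.null, logical(1))]
}

#' @export
print.score_curve <- function(x, ...) {
  cat(sprintf("<score curve> %s [%s] %d points, CE %.1f-%.1f eV\n",
              species_key(x$species), x$channel, length(x$ce),
              min(x$ce), max(x$ce)))
  invisible(x)
}

#' Test curve eligibility
#'
#' @param curve A `score_curve`.
#' @param policy An [eligibility_policy()].
#' @return Logical flag with attribute `"reason"` (empty when eligible).
#' @export
is_eligible <- function(curve, policy = eligibility_policy()) {
  thr <- policy$min_score[[curve$channel]]
  reason <- character(0)
  if (!length(curve$score) || max(curve$score) <= thr)
    reason <- c(reason, "below score threshold")
  grid_idx <- vapply(curve$scale_pct, function(s)
    which.min(abs(as.numeric(curve$grid) - s)), integer(1))
  above <- sort(grid_idx[curve$score > thr])
  best_run <- if (length(above)) {
    runs <- split(above, cumsum(c(1L, diff(above) != 1L)))
    max(lengths(runs))
  } else 0L
  if (best_run < policy$min_consecutive)
    reason <- c(reason, "consecutive-run requirement")
  if (length(curve$ce) < policy$min_points)
    reason <- c(reason, "too few points")
  structure(length(reason) == 0L, reason = reason)
}

# One Levenberg-Marquardt step target: residuals and Jacobian of
# s(ce) = A exp(-(ce-mu)^2 / (2 sigma^2)).
.gauss_eval <- function(theta, x) {
  A <- theta[1]; mu <- theta[2]; sigma <- theta[3]
  u <- (x - mu) / sigma
  e <- exp(-0.5 * u^2)
  list(f = A * e,
       J = cbind(e, A * e * u / sigma, A * e * u^2 / sigma))
}

#' Fit a Gaussian score response
#'
#' Least-squares fit of `s(CE) = A exp(-(CE - mu)^2 / (2 sigma^2))` by
#' damped (Levenberg-Marquardt) nonlinear least squares. Initialization:
#' A = max score, mu = CE of the maximum, sigma = a quarter of the probed
#' CE span. Convergence: relative RSS change below `tol` (default 1e-10)
#' or 200 iterations. The fit is flagged non-converged (not an error) if
#' the solver stalls on a singular system or the center escapes the probed
#' CE range by more than two fitted sigmas.
#'
#' @param curve A `score_curve`, or a list with numeric `ce` and `score`.
#' @param tol Relative RSS convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A `gaussian_fit` object: `amplitude`, `center_ce`,
#'   `width_sigma`, `rss`, `n_points`, `converged`, `iterations`.
#' @export
fit_gaussian <- function(curve, tol = 1e-10, max_iter = 200) {
  x <- curve$ce
  y <- curve$score
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 4L) stop("Gaussian fit requires at least 4 points")
  span <- diff(range(x))
  theta <- c(max(y), x[which.max(y)], max(span / 4, 1e-3))
  ev <- .gauss_eval(theta, x)
  rss <- sum((y - ev$f)^2)
  lambda <- 1e-3
  iter <- 0L
  singular <- FALSE
  done <- FALSE
  while (!done && iter < max_iter) {
    iter <- iter + 1L
    r <- y - ev$f
    JtJ <- crossprod(ev$J)
    g <- crossprod(ev$J, r)
    improved <- FALSE
    for (k in 1:30) {
      step <- try(solve(JtJ + lambda * diag(diag(JtJ), 3), g),
                  silent = TRUE)
      if (inherits(step, "try-error") || any(!is.finite(step))) {
        lambda <- lambda * 10
        next
      }
      cand <- theta + as.numeric(step)
      cand[3] <- abs(cand[3])
      if (cand[3] < 1e-8) cand[3] <- 1e-8
      ev_cand <- .gauss_eval(cand, x)
      rss_cand <- sum((y - ev_cand$f)^2)
      if (is.finite(rss_cand) && rss_cand <= rss) {
        improved <- TRUE
        drop_rel <- (rss - rss_cand) / max(rss, .Machine$double.eps)
        theta <- cand; ev <- ev_cand; rss <- rss_cand
        lambda <- max(lambda / 10, 1e-12)
        if (drop_rel < tol) done <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) { singular <- lambda > 1e12; break }
  }
  in_range <- theta[2] >= min(x) - 2 * theta[3] &&
    theta[2] <= max(x) + 2 * theta[3]
  structure(list(amplitude = theta[1], center_ce = theta[2],
                 width_sigma = theta[3], rss = rss,
                 n_points = length(x),
                 converged = !singular && is.finite(rss) && in_range,
                 iterations = iter),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian fit> A=%.3g  center=%.3f eV  sigma=%.3f eV  (n=%d, %s)\n",
              x$amplitude, x$center_ce, x$width_sigma, x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Optimal collision energy of a fitted curve
#'
#' The optimal CE is the center of the fitted Gaussian. Non-converged fits
#' signal an error: the species is excluded from downstream analysis.
#'
#' @param fit A `gaussian_fit`.
#' @return Energy in eV.
#' @export
optimal_ce <- function(fit) {
  stopifnot(inherits(fit, "gaussian_fit"))
  if (!fit$converged)
    stop("Gaussian fit did not converge; species excluded from analysis")
  fit$center_ce
}

#' Fit all eligible curves and tabulate optima
#'
#' Applies the eligibility policy, fits each eligible curve, and returns
#' one row per converged fit. Ineligible and non-converged curves are
#' dropped; counts are reported in attributes `"n_ineligible"` and
#' `"n_nonconverged"`.
#'
#' @param curves List of `score_curve` objects from [build_curves()].
#' @param policy An [eligibility_policy()].
#' @return Data frame: `species_key`, `sequence`, `glycan_composition`,
#'   `charge`, `channel`, `mz`, `optimal_ce_ev`, `sigma_ev`, `amplitude`,
#'   `n_points`, `converged`.
#' @export
fit_optima <- function(curves, policy = eligibility_policy()) {
  n_inel <- 0L; n_noncv <- 0L
  rows <- lapply(curves, function(cu) {
    if (!is_eligible(cu, policy)) { n_inel <<- n_inel + 1L; return(NULL) }
    fit <- fit_gaussian(cu)
    if (!fit$converged) { n_noncv <<- n_noncv + 1L; return(NULL) }
    data.frame(species_key = species_key(cu$species),
               sequence = cu$species$sequence,
               glycan_composition =
                 format_glycan_composition(cu$species$glycan),
               charge = cu$species$charge, channel = cu$channel,
               mz = cu$mz, optimal_ce_ev = fit$center_ce,
               sigma_ev = fit$width_sigma, amplitude = fit$amplitude,
               n_points = fit$n_points, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species_key = character(0), sequence = character(0),
                      glycan_composition = character(0), charge = integer(0),
                      channel = character(0), mz = numeric(0),
                      optimal_ce_ev = numeric(0), sigma_ev = numeric(0),
                      amplitude = numeric(0), n_points = integer(0),
                      converged = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_ineligible") <- n_inel
  attr(out, "n_nonconverged") <- n_noncv
  out
}
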