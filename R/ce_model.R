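# Instrument collision-energy model: m/z-dependent reference line, the
# percentage sweep, and the hardware ceiling.

#' Collision-energy calibration
#'
#' The instrument applies a collision energy that is linear in precursor
#' m/z, defined by two anchor points and truncated at a hardware ceiling.
#' The default — 50 eV at m/z 600 and 135 eV at m/z 2000, ceiling 200 eV —
#' is the 100% reference setting of a QTof glycopeptide method.
#'
#' @param anchor_low,anchor_high Numeric `c(mz, energy)` pairs in (Th, eV).
#' @param ceiling Maximum settable energy in eV.
#' @param floor Minimum physical energy in eV (guards linear extrapolation
#'   at very low m/z).
#' @return A `ce_calibration` object.
#' @export
ce_calibration <- function(anchor_low = c(600, 50),
                           anchor_high = c(2000, 135),
                           ceiling = 200, floor = 1) {
  stopifnot(length(anchor_low) == 2L, length(anchor_high) == 2L)
  if (anchor_low[1] >= anchor_high[1])
    stop("anchor_low m/z must be below anchor_high m/z")
  if (anchor_low[2] <= 0 || anchor_high[2] <= 0)
    stop("anchor energies must be positive")
  if (ceiling < anchor_high[2])
    stop("ceiling must be at least the high-anchor energy")
  structure(list(anchor_low = as.numeric(anchor_low),
                 anchor_high = as.numeric(anchor_high),
                 ceiling = ceiling, floor = floor),
            class = "ce_calibration")
}

#' @export
print.ce_calibration <- function(x, ...) {
  cat(sprintf("<CE calibration> %g eV @ m/z %g  ->  %g eV @ m/z %g (ceiling %g eV)\n",
              x$anchor_low[2], x$anchor_low[1],
              x$anchor_high[2], x$anchor_high[1], x$ceiling))
  invisible(x)
}

#' Reference collision energy at 100%
#'
#' Linear interpolation through the two calibration anchors, extended
#' linearly outside the anchor interval and floored at `cal$floor`. No
#' ceiling is applied here; the ceiling acts on the scaled energy in
#' [applied_ce()].
#'
#' @param mz Precursor m/z in Th (vectorized).
#' @param cal A [ce_calibration()].
#' @return Energy in eV.
#' @examples
#' reference_ce(600)   # 50
#' reference_ce(2000)  # 135
#' @export
reference_ce <- function(mz, cal = ce_calibration()) {
  stopifnot(inherits(cal, "ce_calibration"))
  if (any(mz <= 0)) stop("m/z must be positive")
  slope <- (cal$anchor_high[2] - cal$anchor_low[2]) /
    (cal$anchor_high[1] - cal$anchor_low[1])
  e <- cal$anchor_low[2] + slope * (mz - cal$anchor_low[1])
  pmax(cal$floor, e)
}

#' Applied collision energy at a sweep setting
#'
#' `min(ceiling, scale_pct/100 * reference_ce(mz))`: the percentage setting
#' scales the reference line, and the instrument truncates at its hardware
#' ceiling.
#'
#' @param mz Precursor m/z in Th.
#' @param scale_pct Sweep setting in percent (100 = reference).
#' @param cal A [ce_calibration()].
#' @return Energy in eV. Arguments are vectorized and recycled.
#' @examples
#' applied_ce(2000, 175)  # 200: 236.25 truncated at the ceiling
#' @export
applied_ce <- function(mz, scale_pct, cal = ce_calibration()) {
  if (any(scale_pct <= 0)) stop("scale percentage must be positive")
  pmin(cal$ceiling, scale_pct / 100 * reference_ce(mz, cal))
}

#' Collision-energy sweep grid
#'
#' Arithmetic progression of percentage settings, `start, start+step, ...`,
#' inclusive of `stop` when exactly reached (tolerance 1e-9 on the grid
#' arithmetic). The default is the 28-setting sweep 6.25–175% in steps of
#' 6.25%; `drop` removes named settings to emulate shorter series (e.g. a
#' 27-run experiment).
#'
#' @param start_pct,stop_pct,step_pct Grid bounds and step in percent.
#' @param drop Optional numeric vector of settings to remove.
#' @return Numeric vector of class `ce_sweep_grid`, strictly increasing.
#' @examples
#' length(sweep_grid())  # 28
#' @export
sweep_grid <- function(start_pct = 6.25, stop_pct = 175, step_pct = 6.25,
                       drop = NULL) {
  if (start_pct <= 0 || step_pct <= 0 || stop_pct < start_pct)
    stop("invalid sweep grid bounds")
  n <- floor((stop_pct - start_pct) / step_pct + 1e-9)
  grid <- start_pct + step_pct * (0:n)
  if (!is.null(drop))
    grid <- grid[!vapply(grid, function(g)
      any(abs(g - drop) < 1e-9), logical(1))]
  if (!length(grid)) stop("sweep grid is empty after dropping settings")
  structure(grid, class = "ce_sweep_grid")
}
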