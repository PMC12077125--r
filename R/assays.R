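# Plate-assay calibrations: qPCR absolute quantification from a serial
# dilution standard curve, BCECF ratiometric pH readout, and OD growth
# summaries.

#' Fit a qPCR standard curve from serial dilutions
#'
#' Least-squares line `Cq = intercept + slope * log10(concentration)` over
#' dilution points. Amplification efficiency follows from the slope as
#' `10^(-1/slope) - 1` (a slope of -log10(2)^-1 = -3.3219 cycles per
#' decade is 100% efficiency); efficiencies outside \[0.9, 1.1\] are
#' flagged. The limit of detection defaults to the lowest concentration at
#' which every replicate amplified.
#'
#' @param concentration concentrations (CFU/mL), >= 3 points spanning at
#'   least 2 decades.
#' @param cq measured quantification cycles; `NA` = no amplification.
#' @return object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `efficiency_ok`, `lod`.
#' @export
fit_standard_curve <- function(concentration, cq) {
  if (length(concentration) != length(cq)) stop("lengths differ")
  amplified <- !is.na(cq)
  conc_a <- concentration[amplified]
  cq_a <- cq[amplified]
  if (length(unique(conc_a)) < 3) stop("insufficient dilution points (need >= 3)")
  lg <- log10(conc_a)
  if (diff(range(lg)) < 2) stop("dilutions must span at least 2 log10 units")
  fit <- stats::lm(cq_a ~ lg)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) stop("positive slope: Cq must decrease with concentration")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq_a - mean(cq_a))^2)
  efficiency <- 10^(-1 / slope) - 1
  # LOD: lowest dilution whose replicates all amplified
  amplified_all <- tapply(amplified, concentration, all)
  detectable <- as.numeric(names(amplified_all))[amplified_all]
  lod <- if (length(detectable)) min(detectable) else NA_real_
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = efficiency,
         efficiency_ok = efficiency >= 0.9 && efficiency <= 1.1,
         lod = lod),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> Cq = %.3f %+.4f log10(CFU/mL)  (R2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  efficiency %.1f%%%s; LOD %s CFU/mL\n", 100 * x$efficiency,
              if (x$efficiency_ok) "" else " [outside 90-110%]",
              format(x$lod, big.mark = ",")))
  invisible(x)
}

#' Absolute quantification from a fitted standard curve
#'
#' Inverts the standard curve, `conc = 10^((cq - intercept)/slope)`.
#' Estimates below the curve's limit of detection are censored at the LOD
#' and flagged.
#'
#' @param cq quantification cycle(s).
#' @param curve a [fit_standard_curve()] result.
#' @return data.frame with columns `cq`, `concentration` (CFU/mL),
#'   `censored`.
#' @export
quantify_absolute <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(!is.finite(cq))) stop("non-finite Cq")
  conc <- 10^((cq - curve$intercept) / curve$slope)
  censored <- rep(FALSE, length(conc))
  if (!is.na(curve$lod)) {
    censored <- conc < curve$lod
    conc[censored] <- curve$lod
  }
  data.frame(cq = cq, concentration = conc, censored = censored)
}

#' Ratiometric BCECF pH readout
#'
#' Converts a 405/475 nm fluorescence ratio to pH by linear interpolation
#' between two calibration points. Within the buffered fermentation range
#' (pH 5.8-6.8) the dye response is close to linear; values interpolated
#' beyond the calibrated range are flagged with a warning.
#'
#' @param f405,f475 fluorescence intensities; `f475` must be > 0.
#' @param calib data.frame or matrix with columns `ratio` and `ph` giving
#'   two (or more) calibration points with distinct ratios.
#' @return pH value(s); attribute `extrapolated` marks readings outside
#'   the calibrated pH range.
#' @export
bcecf_ph <- function(f405, f475, calib) {
  if (any(f475 <= 0)) stop("f475 must be positive")
  calib <- as.data.frame(calib)
  if (!all(c("ratio", "ph") %in% names(calib))) {
    stop("calib needs 'ratio' and 'ph' columns")
  }
  if (nrow(calib) < 2 || anyDuplicated(calib$ratio)) {
    stop("need at least 2 calibration points with distinct ratios")
  }
  calib <- calib[order(calib$ratio), ]
  ratio <- f405 / f475
  # linear interpolation with linear extension beyond the calibrated range
  slope_lo <- (calib$ph[2L] - calib$ph[1L]) / (calib$ratio[2L] - calib$ratio[1L])
  nr <- nrow(calib)
  slope_hi <- (calib$ph[nr] - calib$ph[nr - 1L]) / (calib$ratio[nr] - calib$ratio[nr - 1L])
  ph <- stats::approx(calib$ratio, calib$ph, xout = ratio, rule = 1)$y
  below <- ratio < min(calib$ratio); above <- ratio > max(calib$ratio)
  ph[below] <- calib$ph[1L] + slope_lo * (ratio[below] - calib$ratio[1L])
  ph[above] <- calib$ph[nr] + slope_hi * (ratio[above] - calib$ratio[nr])
  extrapolated <- below | above | ph < min(calib$ph) | ph > max(calib$ph)
  if (any(extrapolated)) {
    warning(sum(extrapolated), " reading(s) outside the calibrated pH range")
  }
  attr(ph, "extrapolated") <- extrapolated
  ph
}

#' Summarize an OD600 growth series
#'
#' Blank-subtracted growth summary using the first time point as blank:
#' final OD, maximum OD, and the net change from t0.
#'
#' @param time_h time points (hours), strictly increasing.
#' @param od600 matching absorbance readings (>= 2 points).
#' @return list with `final_od`, `max_od`, `delta_od` (all blank-
#'   subtracted) and `t0_od`.
#' @export
growth_summary <- function(time_h, od600) {
  if (length(time_h) != length(od600)) stop("lengths differ")
  if (length(time_h) < 2) stop("need at least 2 time points")
  if (is.unsorted(time_h, strictly = TRUE)) stop("time points must be strictly increasing")
  blank <- od600[1L]
  list(final_od = od600[length(od600)] - blank,
       max_od = max(od600) - blank,
       delta_od = od600[length(od600)] - blank,
       t0_od = blank)
}
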