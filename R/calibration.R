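#' Background subtraction
#'
#' The demodulated amplitude of a blank (solvent-only, source on) contains
#' the modulated background — excitation leakage through the emission
#' filter plus filter auto-fluorescence — and must be subtracted from
#' every sample reading before calibration. Sub-blank results are
#' preserved as negative values, not clipped: they carry information about
#' the noise floor.
#'
#' @param r2 Demodulated amplitude(s), a.u.
#' @param r2_blank Blank amplitude, a.u.
#' @return \code{r2 - r2_blank}.
#' @examples
#' background_subtract(25.0, 22.6438)  # 2.3562
#' @export
background_subtract <- function(r2, r2_blank) {
  if (!is.numeric(r2) || !is.numeric(r2_blank)) stop_invalid("inputs must be numeric")
  r2 - r2_blank
}

blank_mean_of <- function(blank) {
  if (is.data.frame(blank)) {
    if (!"r2_mean" %in% names(blank) || nrow(blank) != 1L) {
      stop_invalid("`blank` must be a single measurement record or a number")
    }
    blank$r2_mean
  } else if (is_scalar_num(blank)) {
    blank
  } else {
    stop_invalid("`blank` must be a single measurement record or a number")
  }
}

check_records <- function(records) {
  need <- c("concentration_M", "r2_mean")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_invalid("`records` must be a data frame with columns concentration_M and r2_mean")
  }
  if (any(records$concentration_M < 0)) stop_invalid("negative concentrations")
  records
}

#' Through-origin calibration fit
#'
#' Least-squares fit of the background-subtracted amplitudes to a line
#' through the origin, \code{y = slope * c}: the model implied by a
#' fluorescence signal strictly proportional to fluorophore
#' concentration once the blank has been removed. The closed-form
#' estimator is \code{slope = sum(c*y)/sum(c^2)} (optionally weighted by
#' \code{1/sd^2}), and the goodness of fit is
#' \code{R^2 = 1 - SS_res/SS_tot} with \code{SS_tot} taken about the mean
#' of the included \code{y}.
#'
#' @param records Data frame of measurement records (columns
#'   \code{concentration_M}, \code{r2_mean}, optionally \code{r2_sd});
#'   the blank itself should not be among them.
#' @param blank The blank record (one-row data frame) or its mean
#'   amplitude as a number.
#' @param c_max Only records with \code{concentration_M <= c_max} enter
#'   the fit (default all); use the linear-range bound to exclude the
#'   self-quenched regime.
#' @param weighted If \code{TRUE}, weight each record by
#'   \code{1/r2_sd^2}. Off by default.
#' @return A list with \code{slope} (a.u. per molar) and \code{r_squared}.
#' @examples
#' rec <- data.frame(concentration_M = c(1, 2, 4) * 1e-6,
#'                   r2_mean = 5 + c(1, 2, 4) * 0.35)
#' fit_through_origin(rec, blank = 5)  # slope 3.5e5, R^2 = 1
#' @export
fit_through_origin <- function(records, blank, c_max = Inf, weighted = FALSE) {
  records <- check_records(records)
  b <- blank_mean_of(blank)
  keep <- records$concentration_M <= c_max
  records <- records[keep, , drop = FALSE]
  if (nrow(records) < 2L) {
    stop_invalid("insufficient data: need at least 2 records at or below `c_max`")
  }
  cc <- records$concentration_M
  if (all(cc == 0) || length(unique(cc)) < 2L) {
    stop_invalid("degenerate design: concentrations do not span a range")
  }
  y <- background_subtract(records$r2_mean, b)
  w <- if (weighted) {
    sd <- records$r2_sd
    if (is.null(sd) || any(sd <= 0)) stop_invalid("weighted fit needs positive r2_sd")
    1 / sd^2
  } else {
    rep(1, length(y))
  }
  slope <- sum(w * cc * y) / sum(w * cc^2)
  ss_res <- sum(w * (y - slope * cc)^2)
  ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope = slope, r_squared = r_squared)
}

#' Two-sigma detection limit
#'
#' The smallest concentration regarded as distinguishable from the blank:
#' the point where the corrected signal \code{slope * c} equals twice the
#' blank's standard deviation, i.e. \code{LOD = 2 * sigma_blank / slope}.
#'
#' @param slope Calibration sensitivity, a.u. per molar (> 0).
#' @param sigma_blank Standard deviation of repeated blank readings, a.u.
#'   (>= 0).
#' @return Detection limit in mol/L.
#' @examples
#' detection_limit(1e5, 0.005)  # 1e-7 M
#' @export
detection_limit <- function(slope, sigma_blank) {
  if (!is_scalar_num(slope) || slope <= 0) {
    stop_invalid("invalid calibration: `slope` must be positive")
  }
  if (!is_scalar_num(sigma_blank) || sigma_blank < 0) {
    stop_invalid("`sigma_blank` must be >= 0")
  }
  2 * sigma_blank / slope
}

#' Upper bound of the linear range
#'
#' Scans the dilution series upward from the lowest concentration and
#' returns the largest concentration whose background-subtracted mean
#' stays within a relative tolerance of the through-origin line
#' \code{slope * c}, requiring every lower concentration to pass as well
#' (the scan stops at the first failure). With the saturable
#' self-quenching response \code{c/(1 + c/q)} and the default 5%
#' criterion the bound falls at \code{c = q/19}.
#'
#' @param records Measurement records sorted (or sortable) by
#'   concentration, blank excluded.
#' @param blank Blank record or mean amplitude.
#' @param slope Calibration sensitivity against which deviations are
#'   judged.
#' @param tol Relative deviation tolerance (default 0.05).
#' @return The largest passing concentration in mol/L (the highest tested
#'   concentration if all pass); \code{NA} with a warning if even the
#'   lowest tested concentration deviates by more than \code{tol}.
#' @export
linear_range_max <- function(records, blank, slope, tol = 0.05) {
  records <- check_records(records)
  if (nrow(records) < 1L) stop_invalid("insufficient data: no records")
  if (!is_scalar_num(slope) || slope <= 0) stop_invalid("`slope` must be positive")
  records <- records[order(records$concentration_M), , drop = FALSE]
  cc <- records$concentration_M
  if (any(cc <= 0)) stop_invalid("exclude the blank from `records`")
  y <- background_subtract(records$r2_mean, blank_mean_of(blank))
  rel_dev <- abs(y - slope * cc) / (slope * cc)
  pass <- rel_dev <= tol
  if (!pass[1L]) {
    warning("lowest tested concentration already deviates from the line; no linear range",
            call. = FALSE)
    return(NA_real_)
  }
  first_fail <- which(!pass)
  if (length(first_fail) == 0L) return(cc[length(cc)])
  cc[first_fail[1L] - 1L]
}

#' Dynamic range of the assay
#'
#' Ratio of the largest concentration in the linear range to the smallest
#' detectable concentration.
#'
#' @param linear_range_max Upper linear-range bound, mol/L.
#' @param lod Detection limit, mol/L (> 0).
#' @return Dimensionless ratio.
#' @examples
#' dynamic_range(0.35e-3, 18e-9)  # ~1.9e4
#' @export
dynamic_range <- function(linear_range_max, lod) {
  if (!is_scalar_num(linear_range_max) || linear_range_max < 0) {
    stop_invalid("`linear_range_max` must be >= 0")
  }
  if (!is_scalar_num(lod) || lod <= 0) stop_invalid("invalid detection limit: must be > 0")
  linear_range_max / lod
}

#' Full calibration analysis of a dilution series
#'
#' Runs the complete characterisation on a table of measurement records
#' whose first zero-concentration row is the blank: background
#' subtraction, through-origin sensitivity fit, 2-sigma detection limit,
#' linear-range bound and dynamic range.
#'
#' When \code{c_max} is not given, the linear range is judged against the
#' low-concentration asymptote: a slope is first fitted to the lowest
#' three concentrations (the most reliably linear part of any dilution
#' series), the linear-range bound is located against that slope with
#' \code{\link{linear_range_max}}, and the reported sensitivity and R^2
#' come from a refit over the linear range only. Anchoring the scan at
#' low concentration stops the bound from creeping into the
#' self-quenched regime, where a refitted (and therefore slightly
#' depressed) slope would otherwise re-admit sublinear points.
#'
#' @param records Data frame with columns \code{concentration_M},
#'   \code{r2_mean}, \code{r2_sd}, \code{n_readings}; exactly one row
#'   with concentration 0 (the blank) plus at least two positive
#'   concentrations.
#' @param c_max Optional fixed upper concentration bound for the fit.
#' @param tol Linear-range relative-deviation tolerance (default 0.05).
#' @param weighted Passed to \code{\link{fit_through_origin}}.
#' @return An object of class \code{"calibration_result"}: list with
#'   \code{sensitivity} (a.u./M), \code{r_squared}, \code{lod_2sigma}
#'   (M), \code{linear_range_max} (M), \code{dynamic_range},
#'   \code{blank_mean}, \code{blank_sd}, \code{n_points}.
#' @export
calibrate <- function(records, c_max = NULL, tol = 0.05, weighted = FALSE) {
  records <- check_records(records)
  is_blank <- records$concentration_M == 0
  if (!any(is_blank)) stop_invalid("no blank: include one record with concentration 0")
  blank <- records[which(is_blank)[1L], , drop = FALSE]
  samples <- records[!is_blank, , drop = FALSE]
  samples <- samples[order(samples$concentration_M), , drop = FALSE]
  if (nrow(samples) < 2L) stop_invalid("insufficient data: need >= 2 non-blank records")

  if (!is.null(c_max)) {
    fit <- fit_through_origin(samples, blank, c_max = c_max, weighted = weighted)
    lin_max <- linear_range_max(samples, blank, fit$slope, tol = tol)
  } else {
    n0 <- min(3L, nrow(samples))
    fit0 <- fit_through_origin(samples[seq_len(n0), , drop = FALSE], blank,
                               weighted = weighted)
    lin_max <- linear_range_max(samples, blank, fit0$slope, tol = tol)
    fit <- if (is.na(lin_max)) fit0 else {
      fit_through_origin(samples, blank, c_max = lin_max, weighted = weighted)
    }
  }
  sigma_b <- blank$r2_sd
  lod <- detection_limit(fit$slope, sigma_b)
  dr <- if (!is.na(lin_max) && lod > 0) dynamic_range(lin_max, lod) else NA_real_
  structure(list(sensitivity = fit$slope,
                 r_squared = fit$r_squared,
                 lod_2sigma = lod,
                 linear_range_max = lin_max,
                 dynamic_range = dr,
                 blank_mean = blank$r2_mean,
                 blank_sd = sigma_b,
                 n_points = nrow(samples)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result\n")
  cat(sprintf("  sensitivity      : %.4g a.u./M\n", x$sensitivity))
  cat(sprintf("  R^2              : %.4f\n", x$r_squared))
  cat(sprintf("  2-sigma LOD      : %.4g M\n", x$lod_2sigma))
  cat(sprintf("  linear range max : %.4g M\n", x$linear_range_max))
  cat(sprintf("  dynamic range    : %.4g\n", x$dynamic_range))
  cat(sprintf("  blank            : %.6g +/- %.2g a.u. (%d points fitted)\n",
              x$blank_mean, x$blank_sd, x$n_points))
  invisible(x)
}
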