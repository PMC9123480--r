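#' Lock-in demodulator configuration
#'
#' Bundles the fixed parameters of the digital lock-in: the ADC sample rate
#' \code{fs}, the modulation divisor \code{m} (samples per modulation
#' period, so that the modulation frequency is an exact integer fraction
#' \code{f0 = fs/m} of the sample rate), the exponential-filter weight
#' \code{alpha}, the number of cascaded filter stages, and the interval at
#' which demodulated amplitudes are emitted.
#'
#' Either \code{alpha} or the low-pass cut-off frequency \code{fc} may be
#' given; when \code{alpha} is \code{NULL} it is derived from \code{fc} via
#' \code{\link{alpha_from_cutoff}}. The defaults (\code{fs} = 200 kHz,
#' \code{m} = 488, \code{fc} = 0.25 Hz, two stages, 0.1-s output interval)
#' give a 409.84-Hz modulation frequency and a 0.64-s filter time constant.
#'
#' @param fs Sample rate in Hz (positive scalar).
#' @param m Samples per modulation period; a positive even integer >= 4, so
#'   that the source toggles on/off every \code{m/2} samples land on
#'   integer sample indices.
#' @param alpha Exponential-filter weight in (0, 1), or \code{NULL} to
#'   derive it from \code{fc}.
#' @param fc Filter cut-off frequency in Hz; used only when \code{alpha} is
#'   \code{NULL}.
#' @param n_stages Number of cascaded exponential filter stages (>= 1).
#' @param output_interval Interval in seconds between emitted amplitude
#'   values.
#' @return An object of class \code{"demod_config"}: a list with elements
#'   \code{fs}, \code{m}, \code{alpha}, \code{n_stages},
#'   \code{output_interval}.
#' @examples
#' cfg <- demod_config()
#' modulation_frequency(cfg)   # 409.84 Hz
#' cfg$alpha                   # ~7.85e-6
#' @export
demod_config <- function(fs = 200000, m = 488, alpha = NULL, fc = 0.25,
                         n_stages = 2, output_interval = 0.1) {
  if (!is_scalar_num(fs) || fs <= 0) stop_invalid("`fs` must be a positive number")
  if (!is_scalar_num(m) || m < 4 || m %% 2 != 0) {
    stop_invalid("`m` must be an even integer >= 4 (the source toggles every m/2 samples)")
  }
  if (is.null(alpha)) {
    if (!is_scalar_num(fc)) stop_invalid("give either `alpha` or `fc`")
    alpha <- alpha_from_cutoff(fc, fs)
  }
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1) {
    stop_invalid("`alpha` must lie strictly between 0 and 1")
  }
  if (!is_scalar_num(n_stages) || n_stages < 1 || n_stages %% 1 != 0) {
    stop_invalid("`n_stages` must be an integer >= 1")
  }
  if (!is_scalar_num(output_interval) || output_interval <= 0) {
    stop_invalid("`output_interval` must be a positive number of seconds")
  }
  f0 <- fs / m
  fcut <- cutoff_from_alpha(alpha, fs)
  if (f0 < 100 * fcut) {
    warning(sprintf(paste0(
      "modulation frequency f0 = %.3g Hz is less than 100x the filter ",
      "cut-off %.3g Hz; the modulation should sit far outside the filter ",
      "passband for clean demodulation"), f0, fcut), call. = FALSE)
  }
  structure(
    list(fs = fs, m = as.integer(m), alpha = alpha,
         n_stages = as.integer(n_stages), output_interval = output_interval),
    class = "demod_config")
}

#' @export
print.demod_config <- function(x, ...) {
  cat("Digital lock-in configuration\n")
  cat(sprintf("  sample rate fs      : %g Hz\n", x$fs))
  cat(sprintf("  divisor m           : %d  (f0 = fs/m = %.2f Hz)\n",
              x$m, modulation_frequency(x)))
  cat(sprintf("  filter alpha        : %.4g  (fc = %.4g Hz, tau = %.4g s)\n",
              x$alpha, cutoff_from_alpha(x$alpha, x$fs), time_constant(x)))
  cat(sprintf("  filter stages       : %d\n", x$n_stages))
  cat(sprintf("  output interval     : %g s\n", x$output_interval))
  invisible(x)
}

#' Modulation frequency of a lock-in configuration
#'
#' The excitation source is toggled so that one full on/off cycle spans
#' \code{m} samples, giving a modulation frequency \code{f0 = fs/m} that is
#' an exact integer fraction of the sample rate (this phase-locks the
#' references to the signal and avoids timing drift).
#'
#' @param cfg A \code{\link{demod_config}}.
#' @return Modulation frequency in Hz.
#' @examples
#' modulation_frequency(demod_config())  # 409.84 Hz
#' @export
modulation_frequency <- function(cfg) {
  stopifnot(inherits(cfg, "demod_config"))
  cfg$fs / cfg$m
}

#' Conversions between filter weight, cut-off frequency and time constant
#'
#' The single-pole exponential moving-average filter
#' \code{y(n) = y(n-1) + alpha * (x(n) - y(n-1))} has pole \code{1 - alpha}.
#' Matching that pole to a continuous-time RC pole \code{exp(-dt/tau)} gives
#' the exact mappings \code{alpha = 1 - exp(-2*pi*fc/fs)} and
#' \code{fc = -fs * log(1 - alpha) / (2*pi)}, with time constant
#' \code{tau = 1/(2*pi*fc)}. For the small weights used here
#' (\code{alpha ~ 1e-5}) these agree with the first-order approximations
#' \code{alpha = 2*pi*fc/fs} and \code{tau = 1/(fs*alpha)} to better than
#' one part in 1e4.
#'
#' @param fc Cut-off frequency in Hz; must satisfy \code{0 < fc < fs/2}.
#' @param fs Sample rate in Hz.
#' @param alpha Filter weight in (0, 1).
#' @return \code{alpha_from_cutoff}: the filter weight;
#'   \code{cutoff_from_alpha}: the -3 dB cut-off in Hz;
#'   \code{time_constant_from_cutoff}: the time constant in seconds.
#' @examples
#' alpha_from_cutoff(0.25, 200000)       # 7.85e-6
#' time_constant_from_cutoff(0.25)       # 0.637 s
#' cutoff_from_alpha(7.85e-6, 200000)    # ~0.25 Hz
#' @export
alpha_from_cutoff <- function(fc, fs) {
  if (!is.numeric(fc) || !is_scalar_num(fs) || fs <= 0) {
    stop_invalid("`fc` and `fs` must be numeric")
  }
  if (any(fc < 0) || any(fc >= fs / 2)) {
    stop_invalid("`fc` must lie in [0, fs/2)")
  }
  1 - exp(-2 * pi * fc / fs)
}

#' @rdname alpha_from_cutoff
#' @export
cutoff_from_alpha <- function(alpha, fs) {
  if (any(alpha <= 0) || any(alpha >= 1)) stop_invalid("`alpha` must lie in (0, 1)")
  -fs * log(1 - alpha) / (2 * pi)
}

#' @rdname alpha_from_cutoff
#' @export
time_constant_from_cutoff <- function(fc) {
  if (any(fc <= 0)) stop_invalid("`fc` must be positive")
  1 / (2 * pi * fc)
}

#' Filter time constant of a configuration
#'
#' @param cfg A \code{\link{demod_config}}.
#' @return Per-stage filter time constant in seconds.
#' @export
time_constant <- function(cfg) {
  stopifnot(inherits(cfg, "demod_config"))
  time_constant_from_cutoff(cutoff_from_alpha(cfg$alpha, cfg$fs))
}

#' Samples to wait for the lock-in output to settle
#'
#' After power-on, a sample change or a parameter change, the cascaded
#' exponential filters approach their new steady state with per-stage time
#' constant tau; waiting \code{k} time constants (default 10) leaves a
#' two-stage step-response residual of \code{(1 + k) * exp(-k)} (about
#' 5e-4 at k = 10). With the default configuration this is roughly 6.4 s,
#' i.e. about 1.27 million samples at 200 kHz.
#'
#' @param cfg A \code{\link{demod_config}}.
#' @param k Number of time constants to wait (default 10).
#' @return \code{settling_samples}: integer number of samples,
#'   \code{ceiling(k * tau * fs)}; \code{settling_time}: the same horizon
#'   in seconds.
#' @examples
#' settling_time(demod_config())      # ~6.4 s
#' settling_samples(demod_config())   # ~1.27e6
#' @export
settling_samples <- function(cfg, k = 10) {
  stopifnot(inherits(cfg, "demod_config"))
  if (!is_scalar_num(k) || k < 0) stop_invalid("`k` must be a non-negative number")
  as.integer(ceiling(k * time_constant(cfg) * cfg$fs))
}

#' @rdname settling_samples
#' @export
settling_time <- function(cfg, k = 10) {
  stopifnot(inherits(cfg, "demod_config"))
  k * time_constant(cfg)
}
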