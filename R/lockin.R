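#' Quadrature reference signals
#'
#' The two references are a phase-quadrature cosine/sine pair at the
#' modulation frequency, evaluated at sample index \code{n}:
#' \code{qx = cos(2*pi*n/m)}, \code{qy = sin(2*pi*n/m)}. Because the
#' modulation frequency is an exact integer fraction of the sample rate,
#' both are exactly periodic with period \code{m} samples. Using the pair
#' (rather than a single reference) makes the demodulated magnitude
#' independent of the signal's phase, which drifts with the source's
#' turn-on lag.
#'
#' @param n Sample index (vectorised, non-negative integers).
#' @param m Modulation divisor (samples per period, >= 4).
#' @return A list with numeric vectors \code{qx} and \code{qy}.
#' @examples
#' lockin_references(0, 488)    # (1, 0)
#' lockin_references(122, 488)  # (0, 1): quarter period
#' @export
lockin_references <- function(n, m) {
  if (any(n < 0)) stop_invalid("`n` must be non-negative")
  if (!is_scalar_num(m) || m < 4) stop_invalid("`m` must be >= 4")
  # reduce mod m before cospi/sinpi: exact periodicity and full precision
  # even at sample indices in the tens of millions
  frac <- (n %% m) / m
  list(qx = cospi(2 * frac), qy = sinpi(2 * frac))
}

#' Initial demodulator state
#'
#' Running state of the streaming demodulator: the sample index \code{n}
#' and one pair of filter accumulators per cascaded stage, all zero before
#' the first sample.
#'
#' @param cfg A \code{\link{demod_config}}.
#' @return An object of class \code{"demod_state"}: list with integer
#'   \code{n} and numeric vectors \code{x}, \code{y} of length
#'   \code{cfg$n_stages} (stage 1 first).
#' @export
demod_state <- function(cfg) {
  stopifnot(inherits(cfg, "demod_config"))
  structure(list(n = 0L,
                 x = numeric(cfg$n_stages),
                 y = numeric(cfg$n_stages)),
            class = "demod_state")
}

#' Process one sample through the lock-in
#'
#' The streaming update: the incoming sample is multiplied by the two
#' quadrature references evaluated at the current index, each product is
#' passed through the cascade of exponential moving-average filters
#' (\code{acc <- acc + alpha * (input - acc)}, every stage using the same
#' weight), the index advances, and the demodulated amplitude
#' \code{r2 = sqrt(X^2 + Y^2)} of the final stage is returned. A pure
#' function of (state, sample): the same pair always yields the same
#' result.
#'
#' @param state A \code{\link{demod_state}}.
#' @param sample One finite numeric sample (ADC counts or any linear unit).
#' @param cfg The \code{\link{demod_config}} the state was created for.
#' @return A list with elements \code{state} (advanced state) and \code{r2}
#'   (the demodulated amplitude after this sample, same units as the
#'   input).
#' @seealso \code{\link{demodulate}} for the vectorised whole-stream
#'   equivalent.
#' @export
lockin_step <- function(state, sample, cfg) {
  stopifnot(inherits(state, "demod_state"), inherits(cfg, "demod_config"))
  if (!is_scalar_num(sample)) stop_invalid("`sample` must be a single finite number")
  refs <- lockin_references(state$n, cfg$m)
  a <- cfg$alpha
  xin <- refs$qx * sample
  yin <- refs$qy * sample
  for (s in seq_len(cfg$n_stages)) {
    state$x[s] <- state$x[s] + a * (xin - state$x[s])
    state$y[s] <- state$y[s] + a * (yin - state$y[s])
    xin <- state$x[s]
    yin <- state$y[s]
  }
  state$n <- state$n + 1L
  k <- cfg$n_stages
  list(state = state, r2 = sqrt(state$x[k]^2 + state$y[k]^2))
}

#' Demodulate a sample stream
#'
#' Runs the lock-in over a whole stream and emits the demodulated
#' amplitude every \code{output_interval} seconds (every
#' \code{round(fs * output_interval)} samples, instantaneous value, no
#' averaging across the interval). Equivalent to folding
#' \code{\link{lockin_step}} over the stream from the zero state, but
#' executed through vectorised recursive filters so that multi-million
#' sample streams demodulate in well under a second.
#'
#' The output starts from the zero state, so the first
#' \code{\link{settling_time}} seconds of the trace are dominated by the
#' filter step response; discard them (or use
#' \code{\link{measure_stream}}, which does) before quoting amplitudes.
#'
#' @param stream A \code{\link{sample_stream}} (its \code{fs} must equal
#'   \code{cfg$fs}) or a plain numeric vector assumed to be sampled at
#'   \code{cfg$fs}.
#' @param cfg A \code{\link{demod_config}}.
#' @return An object of class \code{"r_trace"}: list with \code{times}
#'   (seconds, at the output interval), \code{values} (demodulated
#'   amplitudes, all >= 0) and \code{output_rate} (Hz). An empty stream
#'   yields an empty trace.
#' @examples
#' cfg <- demod_config(fs = 20000, m = 40, fc = 5)
#' n <- 0:59999
#' tone <- cos(2 * pi * n / 40)          # unit tone at f0
#' tr <- demodulate(tone, cfg)
#' tail(tr$values, 1)                    # -> 0.5 (half the amplitude)
#' @export
demodulate <- function(stream, cfg) {
  stopifnot(inherits(cfg, "demod_config"))
  if (inherits(stream, "sample_stream")) {
    if (abs(stream$fs - cfg$fs) > 1e-9 * cfg$fs) {
      stop_invalid(sprintf(
        "stream sample rate (%g Hz) does not match the configuration (%g Hz)",
        stream$fs, cfg$fs))
    }
    x <- stream$counts
  } else if (is.numeric(stream)) {
    x <- as.numeric(stream)
  } else {
    stop_invalid("`stream` must be a sample_stream or a numeric vector")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_invalid("stream contains non-finite samples (corrupt input)")
  }
  stride <- round_half_up(cfg$fs * cfg$output_interval)
  if (stride < 1) stop_invalid("output interval is shorter than one sample period")
  N <- length(x)
  if (N == 0) {
    return(structure(list(times = numeric(0), values = numeric(0),
                          output_rate = 1 / cfg$output_interval),
                     class = "r_trace"))
  }
  refs <- lockin_references(seq_len(N) - 1, cfg$m)
  a <- cfg$alpha
  xs <- refs$qx * x
  ys <- refs$qy * x
  for (s in seq_len(cfg$n_stages)) {
    # y(n) = y(n-1) + a*(x(n) - y(n-1))  ==  y(n) = a*x(n) + (1-a)*y(n-1)
    xs <- as.numeric(stats::filter(a * xs, 1 - a, method = "recursive"))
    ys <- as.numeric(stats::filter(a * ys, 1 - a, method = "recursive"))
  }
  idx <- seq.int(stride, N, by = stride)
  structure(list(times = idx / cfg$fs,
                 values = sqrt(xs[idx]^2 + ys[idx]^2),
                 output_rate = 1 / cfg$output_interval),
            class = "r_trace")
}

#' @export
print.r_trace <- function(x, ...) {
  cat(sprintf("Lock-in amplitude trace: %d points at %g Hz output rate\n",
              length(x$values), x$output_rate))
  if (length(x$values)) {
    cat(sprintf("  span %.4g s .. %.4g s, final value %.6g a.u.\n",
                x$times[1], x$times[length(x$times)],
                x$values[length(x$values)]))
  }
  invisible(x)
}

#' Settled mean and scatter of a demodulated stream
#'
#' Demodulates a stream, drops the outputs inside the settling horizon
#' (\code{k} time constants from the start), and summarises the remainder
#' as one measurement record: mean amplitude, standard deviation, and the
#' number of output-interval readings averaged. This mirrors the bench
#' procedure of letting the reading stabilise and then recording it for
#' several seconds.
#'
#' @param stream A \code{\link{sample_stream}} or numeric vector.
#' @param cfg A \code{\link{demod_config}}.
#' @param concentration Optional analyte concentration (mol/L) stored in
#'   the returned record.
#' @param k Settling horizon in time constants (default 10).
#' @return A one-row data frame with columns \code{concentration_M},
#'   \code{r2_mean}, \code{r2_sd}, \code{n_readings}.
#' @export
measure_stream <- function(stream, cfg, concentration = NA_real_, k = 10) {
  tr <- demodulate(stream, cfg)
  keep <- tr$times > settling_time(cfg, k)
  if (!any(keep)) {
    stop_invalid("stream is shorter than the settling horizon; nothing to measure")
  }
  v <- tr$values[keep]
  data.frame(concentration_M = concentration,
             r2_mean = mean(v),
             r2_sd = if (length(v) > 1) stats::sd(v) else 0,
             n_readings = length(v))
}
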