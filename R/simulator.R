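#' Fluorophore emission model
#'
#' Maps analyte concentration to the amplitude of the modulated optical
#' signal reaching the photodiode, in volt-equivalent units at the
#' conditioning-circuit input. The dose response is linear at low
#' concentration and rolls off smoothly above \code{quench_scale}, the
#' saturable form \code{sensitivity * c / (1 + c/quench_scale)} standing in
#' for dimerisation-induced self-quenching and inner filtering at high dye
#' concentration. \code{leakage} is a concentration-independent modulated
#' background: excitation light that leaks through the long-pass filter
#' plus filter auto-fluorescence. It is modulated exactly like the
#' fluorescence, so it survives lock-in detection and must be removed by
#' blank subtraction downstream.
#'
#' @param sensitivity Signal amplitude per molar, V/M (>= 0).
#' @param quench_scale Concentration scale of the sublinear roll-off, mol/L
#'   (> 0). With a 5% relative-deviation criterion the linear range ends
#'   near \code{quench_scale/19}.
#' @param leakage Modulated background amplitude, V (>= 0).
#' @return An object of class \code{"emission_model"}.
#' @export
emission_model <- function(sensitivity = 1e5, quench_scale = 7.4e-4,
                           leakage = 0.05) {
  if (!is_scalar_num(sensitivity) || sensitivity < 0) {
    stop_invalid("`sensitivity` must be >= 0")
  }
  if (!is_scalar_num(quench_scale) || quench_scale <= 0) {
    stop_invalid("`quench_scale` must be > 0")
  }
  if (!is_scalar_num(leakage) || leakage < 0) stop_invalid("`leakage` must be >= 0")
  structure(list(sensitivity = sensitivity, quench_scale = quench_scale,
                 leakage = leakage),
            class = "emission_model")
}

#' Modulated emission amplitude for a concentration
#'
#' @param c Analyte concentration, mol/L (vectorised, >= 0).
#' @param em An \code{\link{emission_model}}.
#' @return Signal amplitude in V: \code{sensitivity * c / (1 + c/quench_scale)},
#'   strictly increasing in \code{c} and asymptotically linear as
#'   \code{c -> 0}.
#' @examples
#' em <- emission_model(sensitivity = 1e5, quench_scale = 1e-4)
#' fluorescence_amplitude(1e-4, em)  # half the linear extrapolation
#' @export
fluorescence_amplitude <- function(c, em) {
  stopifnot(inherits(em, "emission_model"))
  if (!is.numeric(c) || any(!is.finite(c))) stop_invalid("`c` must be finite numeric")
  if (any(c < 0)) stop_invalid("negative concentration")
  em$sensitivity * c / (1 + c / em$quench_scale)
}

#' Analogue front-end model
#'
#' Parameters of the simulated signal chain between the photodiode and the
#' demodulator: the DC-compensation servo (a high-pass that treats
#' everything below \code{hp_cutoff} as DC and nulls it, so ambient light
#' cannot saturate the converter), the summing stage that recentres the
#' signal on \code{dc_offset} volts, the second-order anti-aliasing
#' low-pass at \code{lp_cutoff}, and the ADC (12 bits over
#' \code{adc_vref} volts by default). Interference enters as a constant
#' ambient term, a mains sine, and additive white Gaussian noise at the
#' conditioning input. \code{led_tau_on} is the first-order turn-on/off lag
#' of the LED and its driver, which softens the square modulation and
#' shifts its phase — the reason the demodulator uses a quadrature pair.
#'
#' @param led_tau_on LED/driver turn-on time constant, s (>= 0).
#' @param hp_cutoff DC-compensation corner frequency, Hz (default 16).
#' @param lp_cutoff Anti-aliasing corner frequency, Hz (default 94000,
#'   second order); must be below half the sample rate in use.
#' @param dc_offset Offset added after high-pass filtering, V (default 1.6,
#'   centring a bipolar signal in the converter's unipolar range).
#' @param ambient_dc Constant ambient-light level at the input, V.
#' @param mains_freq Mains interference frequency, Hz (default 50).
#' @param mains_amp Mains interference amplitude, V.
#' @param white_sd Standard deviation of the additive white noise, V.
#' @param adc_bits ADC resolution in bits (default 12).
#' @param adc_vref ADC full-scale input voltage, V (default 3.3): 0 V maps
#'   to 0 counts and \code{adc_vref} to \code{2^adc_bits - 1}.
#' @return An object of class \code{"front_end_model"}.
#' @export
front_end_model <- function(led_tau_on = 5e-5, hp_cutoff = 16,
                            lp_cutoff = 94000, dc_offset = 1.6,
                            ambient_dc = 0.2, mains_freq = 50,
                            mains_amp = 0.01, white_sd = 0.003,
                            adc_bits = 12, adc_vref = 3.3) {
  num_ge0 <- function(v, nm) {
    if (!is_scalar_num(v) || v < 0) stop_invalid(sprintf("`%s` must be >= 0", nm))
  }
  num_ge0(led_tau_on, "led_tau_on"); num_ge0(ambient_dc, "ambient_dc")
  num_ge0(mains_amp, "mains_amp"); num_ge0(white_sd, "white_sd")
  if (!is_scalar_num(hp_cutoff) || hp_cutoff <= 0) stop_invalid("`hp_cutoff` must be > 0")
  if (!is_scalar_num(lp_cutoff) || lp_cutoff <= hp_cutoff) {
    stop_invalid("`lp_cutoff` must exceed `hp_cutoff`")
  }
  if (!is_scalar_num(adc_bits) || adc_bits < 1) stop_invalid("`adc_bits` must be >= 1")
  if (!is_scalar_num(adc_vref) || adc_vref <= 0) stop_invalid("`adc_vref` must be > 0")
  structure(list(led_tau_on = led_tau_on, hp_cutoff = hp_cutoff,
                 lp_cutoff = lp_cutoff, dc_offset = dc_offset,
                 ambient_dc = ambient_dc, mains_freq = mains_freq,
                 mains_amp = mains_amp, white_sd = white_sd,
                 adc_bits = as.integer(adc_bits), adc_vref = adc_vref,
                 adc_max = as.integer(2^adc_bits - 1)),
            class = "front_end_model")
}

#' Source modulation waveform
#'
#' The excitation source is driven by a 50%-duty square wave that toggles
#' every \code{m/2} samples (at the zero crossings of the sine reference),
#' ON for the first half-period starting at sample 0. A non-zero
#' \code{led_tau_on} applies the first-order turn-on/off lag of the
#' LED/driver; the returned value is the *periodic steady state* of that
#' lag (closed form in \code{n mod m}), so the waveform remains a pure
#' function of the sample index. The lag reduces the first-harmonic
#' amplitude by \code{1/sqrt(1 + (2*pi*f0*led_tau_on)^2)} and delays its
#' phase by \code{atan(2*pi*f0*led_tau_on)}.
#'
#' @param n Sample index (vectorised, >= 0).
#' @param m Modulation divisor (even, >= 4).
#' @param led_tau_on Turn-on/off time constant in seconds (0 = ideal
#'   square).
#' @param fs Sample rate in Hz (needed only when \code{led_tau_on > 0}).
#' @return Waveform values in [0, 1].
#' @examples
#' modulation_waveform(0:7, 8)          # 1 1 1 1 0 0 0 0
#' @export
modulation_waveform <- function(n, m, led_tau_on = 0, fs = NULL) {
  if (!is_scalar_num(m) || m < 4 || m %% 2 != 0) stop_invalid("`m` must be even and >= 4")
  if (any(n < 0)) stop_invalid("`n` must be non-negative")
  p <- n %% m
  half <- m / 2
  ideal <- as.numeric(p < half)
  if (led_tau_on <= 0) return(ideal)
  if (is.null(fs)) stop_invalid("`fs` is required when `led_tau_on` > 0")
  # periodic steady state of a first-order lag driven by the 0/1 square:
  # decay over one half-period E = exp(-half/(fs*tau)); boundary values
  # w(start of ON) = E/(1+E), w(start of OFF) = 1/(1+E)
  d <- exp(-1 / (fs * led_tau_on))          # per-sample decay
  E <- d^half
  w_on0 <- E / (1 + E)
  w_off0 <- 1 / (1 + E)
  on <- p < half
  w <- numeric(length(p))
  w[on] <- 1 + (w_on0 - 1) * d^p[on]
  w[!on] <- w_off0 * d^(p[!on] - half)
  w
}

#' Quantise volt-equivalent samples to ADC counts
#'
#' Linear map of \code{[0, adc_vref]} volts onto
#' \code{[0, 2^adc_bits - 1]} counts with round-half-up at the midpoints
#' and silent clipping at both rails (aggregate clipping is reported by
#' \code{\link{synthesize}}).
#'
#' @param v Voltages (vectorised).
#' @param fe A \code{\link{front_end_model}}.
#' @return Integer counts in \code{[0, 2^adc_bits - 1]}.
#' @examples
#' fe <- front_end_model()
#' adc_quantize(c(0, 1.65, 3.3, -1), fe)  # 0 2048 4095 0
#' @export
adc_quantize <- function(v, fe) {
  stopifnot(inherits(fe, "front_end_model"))
  counts <- round_half_up(v / fe$adc_vref * fe$adc_max)
  pmin(pmax(counts, 0), fe$adc_max)
}

#' Synthesise a photodetector sample stream
#'
#' Composes the optical and analogue chain into a stream of ADC counts for
#' one sample of concentration \code{c}:
#' \enumerate{
#'   \item modulated optical signal
#'     \code{(fluorescence_amplitude(c) + leakage) * modulation_waveform(n)},
#'   \item plus constant ambient light, a mains sine and white Gaussian
#'     noise,
#'   \item first-order high-pass at \code{hp_cutoff} (the DC-compensation
#'     servo), then second-order Butterworth low-pass at \code{lp_cutoff}
#'     (anti-aliasing),
#'   \item plus \code{dc_offset}, then 12-bit quantisation with clipping.
#' }
#' Deterministic given \code{seed}: the same seed and parameters always
#' produce a bit-identical stream, and the caller's RNG state is left
#' untouched.
#'
#' @param c Analyte concentration, mol/L.
#' @param em An \code{\link{emission_model}}.
#' @param fe A \code{\link{front_end_model}}; \code{lp_cutoff} must be
#'   below \code{cfg$fs/2}.
#' @param cfg A \code{\link{demod_config}} supplying \code{fs} and
#'   \code{m}.
#' @param duration Stream length in seconds (> 0).
#' @param seed Integer seed, or \code{NULL} to draw from the current RNG
#'   stream.
#' @return A \code{\link{sample_stream}} of integer counts with the
#'   generating parameters in \code{metadata}. A warning is raised if more
#'   than 1% of samples clip at either ADC rail.
#' @export
synthesize <- function(c, em, fe, cfg, duration, seed = NULL) {
  stopifnot(inherits(em, "emission_model"), inherits(fe, "front_end_model"),
            inherits(cfg, "demod_config"))
  if (!is_scalar_num(duration) || duration <= 0) {
    stop_invalid("`duration` must be a positive number of seconds")
  }
  fs <- cfg$fs
  if (fe$lp_cutoff >= fs / 2) {
    stop_invalid("front-end `lp_cutoff` must be below the Nyquist frequency fs/2")
  }
  f0 <- modulation_frequency(cfg)
  if (fe$hp_cutoff >= f0) {
    stop_invalid("modulation frequency must sit above the DC-compensation corner `hp_cutoff`")
  }
  N <- round_half_up(fs * duration)
  n <- seq_len(N) - 1
  amp <- fluorescence_amplitude(c, em) + em$leakage
  v <- amp * modulation_waveform(n, cfg$m, fe$led_tau_on, fs) + fe$ambient_dc
  if (fe$mains_amp > 0) {
    v <- v + fe$mains_amp * sin(2 * pi * fe$mains_freq * n / fs)
  }
  if (fe$white_sd > 0) {
    v <- v + with_seed(seed, stats::rnorm(N, sd = fe$white_sd))
  }
  # The bench instrument has been powered long before any reading is
  # taken, so the conditioning filters are run to steady state before the
  # stream starts: prepend a circular warm-up segment spanning ~5 time
  # constants of the slow DC-compensation pole and drop it afterwards.
  warm <- min(N, ceiling(5 * fs / (2 * pi * fe$hp_cutoff)))
  v <- c(v[(N - warm + 1):N], v)
  # DC-compensation servo: first-order bilinear-transform high-pass
  hp <- signal::butter(1, fe$hp_cutoff / (fs / 2), type = "high")
  v <- as.numeric(signal::filter(hp, v))
  # anti-aliasing: second-order Butterworth low-pass
  lp <- signal::butter(2, fe$lp_cutoff / (fs / 2), type = "low")
  v <- as.numeric(signal::filter(lp, v))
  v <- v[(warm + 1):(warm + N)]
  v <- v + fe$dc_offset
  raw <- round_half_up(v / fe$adc_vref * fe$adc_max)
  clipped <- sum(raw < 0 | raw > fe$adc_max)
  if (clipped > 0.01 * N) {
    warning(sprintf("%.1f%% of samples clipped at the ADC rails; reduce the signal or offset",
                    100 * clipped / N), call. = FALSE)
  }
  counts <- pmin(pmax(raw, 0), fe$adc_max)
  sample_stream(counts, fs,
                metadata = list(concentration_M = c, duration_s = duration,
                                seed = seed, emission = unclass(em),
                                front_end = unclass(fe),
                                m = cfg$m, clipped_fraction = clipped / N))
}

#' Counts-per-volt gain of the ADC mapping
#'
#' Convenience scale factor \code{(2^adc_bits - 1)/adc_vref}, used to
#' relate demodulated count amplitudes back to volt-equivalent units.
#'
#' @param fe A \code{\link{front_end_model}}.
#' @return Counts per volt.
#' @export
adc_gain <- function(fe) {
  stopifnot(inherits(fe, "front_end_model"))
  fe$adc_max / fe$adc_vref
}

#' Simulate a serial dilution series
#'
#' Generates and measures a full calibration experiment: a blank (solvent
#' only, i.e. concentration 0 — the modulated leakage background is still
#' present) followed by one stream per concentration, each demodulated and
#' summarised after the settling horizon with \code{\link{measure_stream}}.
#' Per-point seeds are derived from \code{seed} so the whole series is
#' reproducible from one integer.
#'
#' @param concentrations Analyte concentrations in mol/L (excluding the
#'   blank, which is always measured first at 0).
#' @param em,fe,cfg Emission, front-end and demodulator models.
#' @param seed Integer master seed.
#' @param blank_duration Blank record length in seconds *after* settling
#'   (default 10, the bench protocol's ten-second record).
#' @param sample_duration Per-concentration record length after settling,
#'   seconds.
#' @param k Settling horizon in time constants.
#' @return A data frame of measurement records (columns
#'   \code{concentration_M}, \code{r2_mean}, \code{r2_sd},
#'   \code{n_readings}), blank row first — the layout accepted by
#'   \code{\link{calibrate}}.
#' @export
simulate_dilution <- function(concentrations, em, fe, cfg, seed = 1,
                              blank_duration = 10, sample_duration = 2,
                              k = 10) {
  if (!is.numeric(concentrations) || length(concentrations) < 1 ||
      any(concentrations <= 0)) {
    stop_invalid("`concentrations` must be positive (the blank is added automatically)")
  }
  settle <- settling_time(cfg, k)
  base_seed <- (as.numeric(seed) %% 1e6) * 1000   # keep derived seeds < 2^31
  one <- function(ci, dur, point_seed) {
    stream <- synthesize(ci, em, fe, cfg, duration = settle + dur,
                         seed = point_seed)
    measure_stream(stream, cfg, concentration = ci, k = k)
  }
  rows <- vector("list", length(concentrations) + 1L)
  rows[[1L]] <- one(0, blank_duration, base_seed)
  for (i in seq_along(concentrations)) {
    rows[[i + 1L]] <- one(concentrations[i], sample_duration, base_seed + i)
  }
  do.call(rbind, rows)
}
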