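# Shared fixtures: a scaled-down configuration (20 kHz, m = 48, fc = 4 Hz)
# keeps per-test streams to a few tens of thousands of samples while
# preserving the structure of the full 200-kHz instrument: modulation
# >= 100x the filter cut-off and far above the 16-Hz DC-compensation
# corner, anti-aliasing corner just below Nyquist.

scaled_cfg <- function(fc = 4, n_stages = 2) {
  demod_config(fs = 20000, m = 48, fc = fc, n_stages = n_stages)
}

scaled_fe <- function(...) {
  args <- list(lp_cutoff = 9000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(front_end_model, args)
}

quiet_fe <- function(...) {
  # noise- and interference-free front end for deterministic checks
  args <- list(led_tau_on = 0, ambient_dc = 0, mains_amp = 0, white_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scaled_fe, args)
}

# Independent oracle: first-harmonic amplitude by direct Fourier quadrature
# sums over an integer number of periods, halved to match the
# unit-amplitude reference convention of the lock-in.
quadrature_oracle <- function(x, m) {
  P <- (length(x) %/% m) * m
  stopifnot(P >= m)
  x <- x[seq_len(P)]
  n <- seq_len(P) - 1
  a <- 2 * sum(x * cospi(2 * (n %% m) / m)) / P
  b <- 2 * sum(x * sinpi(2 * (n %% m) / m)) / P
  sqrt(a^2 + b^2) / 2
}

# Settled demodulated amplitude of a raw numeric stream (first emitted
# value after k time constants).
settled_r2 <- function(x, cfg, k = 10) {
  tr <- demodulate(x, cfg)
  tail(tr$values, max(1L, sum(tr$times > settling_time(cfg, k))))[1L]
}

# Mean of all emitted values after the settling horizon; averages away
# residual reference-frequency ripple in single-stage configurations.
settled_mean <- function(x, cfg, k = 10) {
  tr <- demodulate(x, cfg)
  mean(tr$values[tr$times > settling_time(cfg, k)])
}

make_tone <- function(cfg, duration, freq = NULL, amplitude = 1, phase = 0) {
  n <- seq_len(round(cfg$fs * duration)) - 1
  if (is.null(freq)) {
    amplitude * cos(2 * pi * (n %% cfg$m) / cfg$m + phase)
  } else {
    amplitude * cos(2 * pi * freq * n / cfg$fs + phase)
  }
}
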