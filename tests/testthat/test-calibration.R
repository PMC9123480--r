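test_that("background subtraction is plain, sign-preserving arithmetic", {
  expect_equal(background_subtract(22.6438, 22.6438), 0)
  expect_equal(background_subtract(7.3, 0), 7.3)
  expect_equal(background_subtract(25.0, 22.6438), 2.3562)
  expect_equal(background_subtract(22.0, 22.6438), -0.6438)  # sub-blank preserved
})

test_that("through-origin fit recovers an exact line and matches lm on noisy data", {
  cc <- c(1, 2, 5, 10) * 1e-6
  rec <- data.frame(concentration_M = cc, r2_mean = 4 + 3.5e5 * cc)
  fit <- fit_through_origin(rec, blank = 4)
  expect_equal(fit$slope, 3.5e5)
  expect_equal(fit$r_squared, 1)

  set.seed(21)
  y <- 3.5e5 * cc + rnorm(4, sd = 0.05)
  recn <- data.frame(concentration_M = cc, r2_mean = 10 + y, r2_sd = rep(0.05, 4))
  fitn <- fit_through_origin(recn, blank = 10)
  lmfit <- lm(y ~ 0 + cc)  # independent reference for the same model
  expect_equal(fitn$slope, unname(coef(lmfit)), tolerance = 1e-10)

  expect_error(fit_through_origin(rec[1, , drop = FALSE], blank = 0), "insufficient")
  dup <- data.frame(concentration_M = c(2e-6, 2e-6), r2_mean = c(1, 1.1))
  expect_error(fit_through_origin(dup, blank = 0), "degenerate")
  zz <- data.frame(concentration_M = c(0, 0), r2_mean = c(1, 2))
  expect_error(fit_through_origin(zz, blank = 0), "degenerate")
})

test_that("fit is scale equivariant and shift invariant", {
  cc <- c(1, 2, 4, 8) * 1e-6
  set.seed(5)
  rec <- data.frame(concentration_M = cc,
                    r2_mean = 20 + 2e5 * cc + rnorm(4, sd = 0.1))
  f1 <- fit_through_origin(rec, blank = 20)
  rec_k <- transform(rec, r2_mean = r2_mean * 3.7)
  f2 <- fit_through_origin(rec_k, blank = 20 * 3.7)
  expect_equal(f2$slope, 3.7 * f1$slope)
  expect_equal(f2$r_squared, f1$r_squared)
  rec_s <- transform(rec, r2_mean = r2_mean + 11.1)
  f3 <- fit_through_origin(rec_s, blank = 20 + 11.1)
  expect_equal(f3$slope, f1$slope)
  expect_equal(f3$r_squared, f1$r_squared)
})

test_that("2-sigma detection limit is 2*sigma/slope and monotone in both", {
  expect_equal(detection_limit(1e5, 0), 0)
  expect_equal(detection_limit(1e5, 0.005), 1e-7)
  expect_error(detection_limit(0, 0.005), "slope|positive")
  sig <- seq(0.001, 0.01, by = 0.003)
  lods <- vapply(sig, function(s) detection_limit(2e5, s), numeric(1))
  expect_true(all(diff(lods) > 0))
  slopes <- c(1e4, 1e5, 1e6)
  expect_true(all(diff(vapply(slopes, detection_limit, numeric(1),
                              sigma_blank = 0.002)) < 0))
})

test_that("linear range bound falls where self-quenching exceeds the tolerance", {
  q <- 7.4e-4
  em <- emission_model(sensitivity = 1e5, quench_scale = q, leakage = 0)
  cc <- q * c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.12)
  rec <- data.frame(concentration_M = cc,
                    r2_mean = 3 + fluorescence_amplitude(cc, em))
  # 5% deviation from the line occurs at c = q/19 ~ 0.0526 q
  expect_equal(linear_range_max(rec, blank = 3, slope = 1e5), 0.05 * q)
  # brute-force scan over the same records reproduces the bound
  dev <- abs(rec$r2_mean - 3 - 1e5 * cc) / (1e5 * cc)
  expect_equal(max(cc[cumsum(dev > 0.05) == 0]), 0.05 * q)

  lin <- data.frame(concentration_M = cc, r2_mean = 2e5 * cc)
  expect_equal(linear_range_max(lin, blank = 0, slope = 2e5), max(cc))
  expect_error(linear_range_max(lin[0, ], blank = 0, slope = 2e5), "insufficient|no records")
  off <- data.frame(concentration_M = cc, r2_mean = 5e5 * cc)
  expect_warning(res <- linear_range_max(off, blank = 0, slope = 1e5), "no linear range")
  expect_true(is.na(res))
})

test_that("dynamic range divides linear-range bound by detection limit", {
  expect_equal(dynamic_range(0.35e-3, 18e-9), 19444.44, tolerance = 1e-6)
  expect_equal(dynamic_range(1e-6, 1e-6), 1)
  expect_equal(dynamic_range(5e-3, 200e-9), 25000)
  expect_error(dynamic_range(1e-3, 0), "detection limit|> 0")
})

test_that("full calibration pipeline recovers generator truth on a synthetic series", {
  cfg <- scaled_cfg()
  em <- emission_model(sensitivity = 1e5, quench_scale = 1, leakage = 0.05)
  fe <- scaled_fe()
  conc <- c(0.5, 1, 2, 4, 6, 8) * 1e-6
  fits <- vapply(1:5, function(s) {
    rec <- simulate_dilution(conc, em, fe, cfg, seed = s,
                             blank_duration = 3, sample_duration = 1)
    calibrate(rec)$sensitivity
  }, numeric(1))
  # truth from the noise-free quadrature oracle, independent of the EMA path
  fe0 <- quiet_fe()
  dur <- 60 * cfg$m / cfg$fs
  ref <- synthesize(4e-6, em, fe0, cfg, duration = dur, seed = 1)
  bl <- synthesize(0, em, fe0, cfg, duration = dur, seed = 1)
  oracle_slope <- (quadrature_oracle(tail(ref$counts, 30 * cfg$m), cfg$m) -
                   quadrature_oracle(tail(bl$counts, 30 * cfg$m), cfg$m)) / 4e-6
  expect_equal(median(fits) / oracle_slope, 1, tolerance = 0.02)
})

test_that("Monte-Carlo exceedance concentration brackets the 2-sigma detection limit", {
  # brute-force LOD: smallest tested concentration whose settled reading
  # exceeds the blank mean by 2 sigma in >95% of seeds
  cfg <- scaled_cfg()
  em <- emission_model(sensitivity = 1e5, quench_scale = 1, leakage = 0.05)
  fe <- scaled_fe(led_tau_on = 0)
  settle15 <- settling_time(cfg, 15)
  read_at <- function(ci, seed) {
    st <- synthesize(ci, em, fe, cfg, duration = settle15 + 2, seed = seed)
    measure_stream(st, cfg, k = 15)$r2_mean
  }
  blanks <- vapply(1:40, function(s) read_at(0, 1000 + s), numeric(1))
  sigma_b <- sd(blanks)
  mu_b <- mean(blanks)
  slope <- {  # quick low-noise slope at one reference point
    r <- read_at(4e-6, 1)
    (r - mu_b) / 4e-6
  }
  lod <- detection_limit(slope, sigma_b)
  grid <- lod * c(0.5, 1, 2, 4)
  frac <- vapply(grid, function(ci) {
    mean(vapply(1:40, function(s) read_at(ci, 2000 + s) > mu_b + 2 * sigma_b,
                logical(1)))
  }, numeric(1))
  brute <- grid[which(frac > 0.95)[1]]
  # the analytic extrapolation and the simulation agree to within a factor ~2
  expect_true(is.finite(brute))
  expect_gt(brute, 0.5 * lod)
  expect_lt(brute, 4 * lod)
})

test_that("calibrate wires blank handling, fit, LOD and ranges together", {
  cc <- c(1, 2, 5, 10, 20, 50) * 1e-6
  q <- 2e-4
  em <- emission_model(sensitivity = 3e5, quench_scale = q, leakage = 0)
  rec <- rbind(
    data.frame(concentration_M = 0, r2_mean = 5, r2_sd = 0.004, n_readings = 100),
    data.frame(concentration_M = cc,
               r2_mean = 5 + fluorescence_amplitude(cc, em),
               r2_sd = 0.01, n_readings = 20))
  res <- calibrate(rec)
  expect_s3_class(res, "calibration_result")
  # the fit runs over the detected linear range, where the saturable
  # response depresses the through-origin slope by up to ~tol
  expect_equal(res$sensitivity, 3e5, tolerance = 0.05)
  expect_equal(res$linear_range_max, 10e-6)  # q/19 = 10.5 uM; grid point below
  expect_equal(res$lod_2sigma, 2 * 0.004 / res$sensitivity)
  expect_lte(res$lod_2sigma, res$linear_range_max)
  expect_equal(res$dynamic_range, res$linear_range_max / res$lod_2sigma)
  expect_lt(res$linear_range_max, q / 19 + 1e-9)
  expect_error(calibrate(rec[-1, ]), "blank")
})
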