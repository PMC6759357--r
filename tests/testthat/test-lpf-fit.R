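# exact filter data on a log grid, for self-consistency checks
filter_data <- function(fc = 2500, K = -10, n = 40, f_lo = 100, f_hi = 16000,
                        offset = 0) {
  f <- 2^seq(log2(f_lo), log2(f_hi), length.out = n)
  list(f = f,
       mag = K + lpf_magnitude_db(f, fc),
       ph = wrap_cycles(offset + lpf_phase_cycles(f, fc)))
}

test_that("noiseless joint fit recovers the corner to 0.1% with the right asymptotes", {
  d <- filter_data(fc = 2500, K = -10, offset = 0.5)
  fit <- fit_first_order_lpf(d$f, d$mag, d$ph)
  expect_equal(fit$corner_frequency_hz, 2500, tolerance = 1e-3)
  expect_equal(fit$gain_db, -10, tolerance = 1e-6)
  expect_equal(fit$polarity_offset_cycles, 0.5)
  expect_equal(fit$explained_variance, 1, tolerance = 1e-9)
  # high-frequency asymptotes of the fitted model
  crv <- lpf_fit_curve(fit, c(1e6, 2e6))
  expect_equal(diff(crv$magnitude_db), -20 * log10(2), tolerance = 1e-3)
  expect_equal(crv$phase_cycles[2] - fit$polarity_offset_cycles, -0.25,
               tolerance = 1e-3)
  # at f = fc: K - 3.01 dB and -0.125 cycles
  at_fc <- lpf_fit_curve(fit, fit$corner_frequency_hz)
  expect_equal(at_fc$magnitude_db, fit$gain_db - 10 * log10(2), tolerance = 1e-6)
  expect_equal(at_fc$phase_cycles - fit$polarity_offset_cycles, -0.125,
               tolerance = 1e-6)
})

test_that("magnitude-only and joint fits agree on exact filter data", {
  d <- filter_data(fc = 1800, K = 3)
  fm <- fit_first_order_lpf(d$f, d$mag)
  fj <- fit_first_order_lpf(d$f, d$mag, d$ph)
  expect_equal(fm$corner_frequency_hz, fj$corner_frequency_hz, tolerance = 1e-6)
  expect_equal(fm$corner_frequency_hz, 1800, tolerance = 1)
})

test_that("two points an octave apart far above the corner give the 6-dB/octave slope", {
  fc <- 100
  f <- c(8000, 16000)
  slope <- diff(lpf_magnitude_db(f, fc)) / diff(log2(f))
  expect_equal(slope, -20 * log10(2), tolerance = 0.01) # -6.02 dB/octave
})

test_that("the fc estimate is robust to the magnitude/phase weighting scale", {
  d <- filter_data(fc = 2500, K = 0, offset = 0.5)
  f20 <- fit_first_order_lpf(d$f, d$mag, d$ph, phase_weight_db_per_cycle = 20)
  f80 <- fit_first_order_lpf(d$f, d$mag, d$ph, phase_weight_db_per_cycle = 80)
  expect_equal(f20$corner_frequency_hz, f80$corner_frequency_hz,
               tolerance = 1e-6) # exact data: invariant
  # noisy data: < 2% shift for a twofold change of s
  withr::with_seed(4, {
    magn <- d$mag + rnorm(length(d$f), 0, 0.5)
    phn <- d$ph + rnorm(length(d$f), 0, 0.0125)
  })
  g40 <- fit_first_order_lpf(d$f, magn, phn, phase_weight_db_per_cycle = 40)
  g80 <- fit_first_order_lpf(d$f, magn, phn, phase_weight_db_per_cycle = 80)
  expect_lt(abs(g80$corner_frequency_hz / g40$corner_frequency_hz - 1), 0.02)
})

test_that("underdetermined fits are rejected", {
  expect_error(fit_first_order_lpf(c(1000, 2000, 3000), c(0, -1, -2)),
               "at least 4")
  f <- c(1000, 1200, 1400, 1600)
  expect_error(fit_first_order_lpf(f, lpf_magnitude_db(f, 2000)), "octaves")
})

test_that("post-hoc correction collapses residual input inequality", {
  st <- desk_stimulus(n = 12, seed = 71)
  st$levels_db_spl <- st$levels_db_spl +
    seq(-2, 2, length.out = 12) # 4-dB residual tilt
  cfg <- desk_sim(seed = 1)
  rec <- simulate_recording(st, cfg, noise = FALSE)
  dp <- correct_combinatorial(measure_dp2(rec))
  eff <- fit_bilinear_levels(dp, band_mode = "parametric")
  dpc <- posthoc_input_correction(dp, eff)
  flat <- dpc$magnitude_db_equalized - lpf_magnitude_db(dpc$frequency_hz, 2500)
  expect_lt(sqrt(mean((flat - mean(flat))^2)), 0.2)
  # a perfectly equalized input yields an identically zero correction
  st0 <- desk_stimulus(n = 10, seed = 72)
  dp0 <- correct_combinatorial(measure_dp2(simulate_recording(st0, cfg, noise = FALSE)))
  eff0 <- fit_bilinear_levels(dp0, band_mode = "parametric")
  dpc0 <- posthoc_input_correction(dp0, eff0)
  expect_equal(dpc0$magnitude_db_equalized, dpc0$magnitude_db_corrected,
               tolerance = 1e-6)
})

test_that("omitting the residual-inequality correction biases the corner downward", {
  # declining residual tilt (middle-ear-like): uncorrected magnitudes fall
  # too fast with frequency, mimicking a lower corner
  st <- desk_stimulus(n = 12, seed = 73)
  cfg <- desk_sim(input_shaping = shaping_tilt(-3, 4000), seed = 1)
  rec <- simulate_recording(st, cfg, noise = FALSE)
  dp <- correct_combinatorial(measure_dp2(rec))
  dp <- predict_phase(dp, polarity = -1)
  eff <- fit_bilinear_levels(dp, band_mode = "parametric")
  dpc <- posthoc_input_correction(dp, eff)
  fit_raw <- fit_first_order_lpf(dpc$frequency_hz, dpc$magnitude_db_corrected)
  fit_cor <- fit_first_order_lpf(dpc$frequency_hz, dpc$magnitude_db_equalized)
  expect_lt(fit_raw$corner_frequency_hz, fit_cor$corner_frequency_hz)
  expect_equal(fit_cor$corner_frequency_hz, 2500, tolerance = 0.01)
})

test_that("corner-vs-CF arithmetic matches the octave-distance convention", {
  expect_equal(round(corner_vs_cf_report(2500, 16000)$octaves_below_cf, 1), 2.7)
  expect_equal(corner_vs_cf_report(8000, 8000)$octaves_below_cf, 0)
  withr::with_seed(2, {
    fc <- runif(5, 2100, 3300)
    cf <- runif(5, 13000, 25000)
  })
  rep5 <- corner_vs_cf_report(fc, cf)
  expect_equal(attr(rep5, "mean_octaves"), mean(log2(cf / fc)))
  expect_lt(abs(attr(rep5, "mean_octaves") - 2.8), 0.4)
})
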