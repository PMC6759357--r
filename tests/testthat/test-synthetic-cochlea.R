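test_that("quadratic nonlinearity follows the cos^2 identities", {
  fs <- 111600
  t <- seq.int(0, fs * 0.05 - 1) / fs
  a <- 0.3
  u <- a * cos(2 * pi * 1200 * t)
  cfg <- sim_config(polarity = +1, c1 = 0, c2 = 1, duration_s = 0.05)
  v <- apply_nonlinearity(u, cfg)
  expect_equal(mean(v), a^2 / 2, tolerance = 1e-12)              # DC
  z <- coherent_dft(v, 2400, fs)
  expect_equal(Mod(z), a^2 / 2, tolerance = 1e-9)                # 2nd harmonic
  # two tones: mixed products carry the full product a1*a2
  u2 <- 0.2 * cos(2 * pi * 4600 * t) + 0.5 * cos(2 * pi * 5400 * t)
  v2 <- apply_nonlinearity(u2, cfg)
  expect_equal(Mod(coherent_dft(v2, 800, fs)), 0.2 * 0.5, tolerance = 1e-9)
  expect_equal(Mod(coherent_dft(v2, 10000, fs)), 0.2 * 0.5, tolerance = 1e-9)
  expect_error(apply_nonlinearity(c(1, NA), cfg))
})

test_that("negative polarity inverts the rectified output", {
  fs <- 111600
  t <- seq.int(0, fs * 0.01 - 1) / fs
  u <- cos(2 * pi * 1000 * t)
  neg <- sim_config(polarity = -1, c1 = 0, c2 = 1, duration_s = 0.01)
  pos <- sim_config(polarity = +1, c1 = 0, c2 = 1, duration_s = 0.01)
  expect_equal(apply_nonlinearity(u, neg), -apply_nonlinearity(u, pos))
  hw <- sim_config(nonlinearity_kind = "half_wave", polarity = -1,
                   duration_s = 0.01)
  vh <- apply_nonlinearity(u, hw)
  expect_true(all(vh <= 0))       # negative-going rectification
  expect_lt(min(vh), -0.99)
})

test_that("first-order low-pass filter matches its closed form", {
  fs <- 111600
  dur <- 0.1
  t <- seq.int(0, fs * dur - 1) / fs
  fc <- 2500
  # at f = fc: -3.01 dB and -0.125 cycles
  x <- cos(2 * pi * fc * t)
  z <- coherent_dft(apply_first_order_lpf(x, fc, fs), fc, fs)
  expect_equal(20 * log10(Mod(z)), -10 * log10(2), tolerance = 1e-9)
  expect_equal(Arg(z) / (2 * pi), -0.125, tolerance = 1e-9)
  # 2.8 octaves above the corner: the 17-dB attenuation arithmetic
  f_hi <- fc * 2^2.8
  expect_equal(-lpf_magnitude_db(f_hi, fc), 17, tolerance = 0.05)
  # DC limit: 0 dB, zero phase
  expect_equal(lpf_magnitude_db(0, fc), 0)
  expect_equal(lpf_phase_cycles(0, fc), 0)
  expect_error(apply_first_order_lpf(x, -1, fs), "positive")
  expect_error(apply_first_order_lpf(x, fs, fs), "Nyquist")
})

test_that("simulated DP2 spectrum matches the brute-force trigonometric oracle", {
  for (N in 2:4) {
    st <- desk_stimulus(n = N, seed = 20 + N)
    st$phases_cycles <- withr::with_seed(N, runif(N))
    cfg <- desk_sim(seed = 1, input_shaping = shaping_tilt(-2, 4000),
                    corner_frequency_hz = 2500)
    rec <- simulate_recording(st, cfg, noise = FALSE)
    dp <- measure_dp2(rec)
    oracle <- quad_dp2_oracle(st, cfg)
    expect_equal(dp$amplitude_nm, oracle$amplitude_nm, tolerance = 1e-6)
    expect_lt(max(abs(wrap_cycles(dp$phase_cycles - oracle$phase_cycles))), 1e-6)
  }
})

test_that("DP2 magnitudes scale bilinearly with parent amplitudes", {
  st <- desk_stimulus(n = 5, seed = 31)
  cfg <- desk_sim(seed = 1)
  dp0 <- measure_dp2(simulate_recording(st, cfg, noise = FALSE))
  st2 <- st
  st2$levels_db_spl[3] <- st2$levels_db_spl[3] + 20 * log10(2) # double a_3
  dp1 <- measure_dp2(simulate_recording(st2, cfg, noise = FALSE))
  dmag <- dp1$magnitude_db - dp0$magnitude_db
  one_parent <- xor(dp0$parent_k == 3, dp0$parent_m == 3) & !dp0$is_second_harmonic
  harm3 <- dp0$is_second_harmonic & dp0$parent_k == 3
  neither <- dp0$parent_k != 3 & dp0$parent_m != 3
  expect_equal(dmag[one_parent], rep(20 * log10(2), sum(one_parent)),
               tolerance = 1e-6)
  expect_equal(dmag[harm3], 40 * log10(2), tolerance = 1e-6)
  expect_equal(dmag[neither], rep(0, sum(neither)), tolerance = 1e-6)
})

test_that("two-tone record through the negative rectifier tracks the inverted envelope", {
  st <- two_tone(duration_s = 0.05)
  cfg <- sim_config(duration_s = 0.05, corner_frequency_hz = 2000,
                    linear_path_gain = 0, seed = 1)
  rec <- simulate_recording(st, cfg, noise = FALSE)
  fs <- rec$sample_rate_hz
  t <- seq.int(0, length(rec$displacement_nm) - 1) / fs
  a <- 2e-5 * 10^(70 / 20)
  env2 <- a^2 * (1 + cos(2 * pi * 800 * t)) # squared envelope / 2
  # low-pass output of -u^2 is anti-correlated with the squared envelope
  # (the 2-kHz filter slightly attenuates and delays the 800-Hz beat)
  expect_lt(cor(rec$displacement_nm, env2), -0.85)
  # and the difference tone at 800 Hz dominates the DP2 spectrum
  dp <- measure_dp2(rec, n_segments = 10)
  expect_equal(dp$frequency_hz[which.max(dp$amplitude_nm)], 800)
})

test_that("a linear cochlea produces no significant DP2s", {
  st <- desk_stimulus(n = 8, seed = 5)
  cfg <- desk_sim(c2 = 0, seed = 2)
  rec <- simulate_recording(st, cfg, noise = FALSE)
  dp <- measure_dp2(rec)
  expect_true(all(dp$amplitude_nm < 1e-9))
  # with noise on, significant calls stay at the false-positive level
  rec2 <- simulate_recording(st, cfg, noise = TRUE)
  dp2 <- measure_dp2(rec2, alpha = 0.001)
  expect_lt(mean(dp2$significant), 0.05)
})

test_that("noise floor realizes the configured spectral density", {
  st <- desk_stimulus(n = 5, seed = 11)
  stn <- st; stn$levels_db_spl <- rep(-400, 5)
  cfg <- desk_sim(seed = 77)
  rec <- simulate_recording(stn, cfg)
  bins <- seq(200, 10190, by = 10) # 1000 bins
  sp <- component_spectrum(rec$displacement_nm, bins, rec$sample_rate_hz)
  # one-sided density from coherent bin amplitudes: A^2/2 * T, in nm^2/Hz
  dens_pm <- sqrt(mean(sp$amplitude_nm^2) / 2 * rec$duration_s) * 1e3
  expect_equal(dens_pm, 30, tolerance = 0.1)
})

test_that("alternative rectifier shapes still produce a rich DP2 spectrum", {
  st <- desk_stimulus(n = 8, seed = 17)
  for (kind in c("half_wave", "boltzmann")) {
    cfg <- desk_sim(nonlinearity_kind = kind, motile_gain = 100,
                    hw_gain = 2, seed = 3)
    rec <- simulate_recording(st, cfg)
    dp <- measure_dp2(rec)
    expect_gt(mean(dp$significant), 0.5)
  }
})

test_that("recordings serialize to CSV with a ground-truth ledger", {
  st <- desk_stimulus(n = 4, seed = 2)
  cfg <- desk_sim(seed = 1, input_shaping = shaping_tilt(-3, 4000))
  rec <- simulate_recording(st, cfg)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording_csv(rec, path)
  expect_true(file.exists(path))
  truth <- jsonlite::read_json(sub("\\.csv$", ".truth.json", path),
                               simplifyVector = TRUE)
  expect_equal(truth$corner_frequency_hz, 2500)
  expect_equal(truth$polarity, -1)
  back <- read.csv(path)
  expect_equal(back$displacement_nm, rec$displacement_nm, tolerance = 1e-9)
})
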