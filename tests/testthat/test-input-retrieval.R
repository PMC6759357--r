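test_that("bilinear inversion recovers a tilted effective input exactly when noiseless", {
  st <- desk_stimulus(n = 12, seed = 51)
  cfg <- desk_sim(input_shaping = shaping_tilt(-3, 4000), seed = 1)
  dp <- correct_combinatorial(measure_dp2(simulate_recording(st, cfg, noise = FALSE)))
  eff <- fit_bilinear_levels(dp, band_mode = "parametric")
  tru <- simulate_recording(st, cfg, noise = FALSE)$truth$effective_input_levels_db
  err <- (eff$levels_db - mean(eff$levels_db)) - (tru - mean(tru))
  expect_lt(sqrt(mean(err^2)), 0.1)
  # the parametric filter proxy also finds the motile corner
  expect_equal(eff$corner_frequency_hz, 2500, tolerance = 0.01)
  # the anchor convention pins the mean level
  expect_equal(mean(eff$levels_db), eff$anchor_db)
})

test_that("a flat effective input is retrieved as flat", {
  st <- desk_stimulus(n = 10, seed = 52)
  cfg <- desk_sim(seed = 1)
  dp <- correct_combinatorial(measure_dp2(simulate_recording(st, cfg, noise = FALSE)))
  eff <- fit_bilinear_levels(dp, band_mode = "parametric")
  expect_lt(diff(range(eff$levels_db)), 1e-3)
  expect_false(any(eff$underdetermined))
  # the octave-band filter proxy is approximate but bounded
  effo <- fit_bilinear_levels(dp)
  expect_lt(diff(range(effo$levels_db)), 2)
})

test_that("a 10-dB primary span doubles in the DP2s and inverts back to 10 dB", {
  st <- desk_stimulus(n = 10, seed = 53)
  st$levels_db_spl <- seq(55, 65, length.out = 10)
  cfg <- desk_sim(corner_frequency_hz = 50000, seed = 1)
  dp <- correct_combinatorial(measure_dp2(simulate_recording(st, cfg, noise = FALSE)))
  flat <- dp$magnitude_db_corrected - lpf_magnitude_db(dp$frequency_hz, 50000)
  expect_equal(diff(range(flat)), 20, tolerance = 1e-6)
  eff <- fit_bilinear_levels(dp, band_mode = "parametric",
                             fc_grid_hz = 2^seq(log2(250), log2(50000), by = 0.1))
  expect_equal(diff(range(eff$levels_db)), 10, tolerance = 0.01)
})

test_that("the level anchor absorbs exactly the gauge freedom", {
  st <- desk_stimulus(n = 8, seed = 54)
  cfg <- desk_sim(seed = 3)
  dp <- correct_combinatorial(measure_dp2(simulate_recording(st, cfg)))
  e1 <- fit_bilinear_levels(dp, anchor_db = 60)
  e2 <- fit_bilinear_levels(dp, anchor_db = 65)
  # shifting the anchor shifts every level by the same constant ...
  expect_equal(e2$levels_db - e1$levels_db, rep(5, 8), tolerance = 1e-9)
  # ... while predictions (hence residuals) are unchanged
  expect_equal(e2$residual_rms_db, e1$residual_rms_db, tolerance = 1e-9)
})

test_that("noisy level retrieval stays within 1 dB RMS over 50 seeds", {
  st <- desk_stimulus(n = 12, seed = 55)
  cfg0 <- desk_sim(input_shaping = shaping_tilt(-4, 4000))
  tru <- simulate_recording(st, cfg0, noise = FALSE)$truth$effective_input_levels_db
  tru <- tru - mean(tru)
  rmse <- sapply(1:50, function(s) {
    cfg <- desk_sim(input_shaping = shaping_tilt(-4, 4000), seed = 1000 + s)
    dp <- correct_combinatorial(measure_dp2(simulate_recording(st, cfg)))
    eff <- fit_bilinear_levels(dp)
    sqrt(mean(((eff$levels_db - mean(eff$levels_db)) - tru)^2))
  })
  expect_lt(sqrt(mean(rmse^2)), 1)
})

test_that("primary phases are recovered up to gauge from DP2 phases", {
  st <- desk_stimulus(n = 10, seed = 56)
  st$phases_cycles <- withr::with_seed(9, runif(10))
  shp <- shaping_table(c(300, 2000, 8000), gain_db = c(0, -2, -6),
                       phase_cycles = c(0.02, -0.05, 0.08))
  cfg <- desk_sim(input_shaping = shp, seed = 1)
  rec <- simulate_recording(st, cfg, noise = FALSE)
  dp <- correct_combinatorial(measure_dp2(rec))
  ph <- fit_primary_phases(dp, polarity = -1, band_mode = "parametric")
  tru <- rec$truth$effective_input_phases_cycles
  err <- wrap_cycles(ph$phases_cycles - tru)
  expect_lt(max(abs(err - mean(err))), 1e-3)
  expect_false(any(ph$low_confidence))
})

test_that("polarity misspecification lands in the constant offset, not the phases", {
  st <- desk_stimulus(n = 8, seed = 57)
  cfg <- desk_sim(polarity = -1, seed = 1)
  dp <- correct_combinatorial(measure_dp2(simulate_recording(st, cfg, noise = FALSE)))
  pa <- fit_primary_phases(dp, polarity = -1, band_mode = "parametric")
  pb <- fit_primary_phases(dp, polarity = +1, band_mode = "parametric")
  expect_lt(max(abs(wrap_cycles(pa$phases_cycles - pb$phases_cycles))), 1e-6)
  expect_equal(abs(wrap_cycles(pa$rho_cycles - pb$rho_cycles)), 0.5,
               tolerance = 1e-6)
})

test_that("equalization is a fixed point on a flat input and flattens a tilt in one step", {
  st <- desk_stimulus(n = 10, seed = 58)
  cfg <- desk_sim(seed = 1)
  dp <- correct_combinatorial(measure_dp2(simulate_recording(st, cfg, noise = FALSE)))
  eff <- fit_bilinear_levels(dp, band_mode = "parametric")
  st2 <- equalization_step(st, eff)
  expect_equal(st2$levels_db_spl, st$levels_db_spl, tolerance = 1e-6)
  # static -6 dB/octave shaping: one noiseless step flattens the input
  cfg6 <- desk_sim(input_shaping = shaping_tilt(-6, 4000), seed = 1)
  src <- function(s) simulate_recording(s, cfg6, noise = FALSE)
  dp0 <- correct_combinatorial(measure_dp2(src(st)))
  e0 <- fit_bilinear_levels(dp0, band_mode = "parametric")
  st1 <- equalization_step(st, e0)
  dp1 <- correct_combinatorial(measure_dp2(src(st1)))
  e1 <- fit_bilinear_levels(dp1, band_mode = "parametric")
  expect_lt(diff(range(e1$levels_db)), 0.2)
  # mean stimulus level is preserved by the renormalization
  expect_equal(mean(st1$levels_db_spl), mean(st$levels_db_spl))
})

test_that("the closed loop terminates, reduces scatter, and respects max_iter", {
  st <- desk_stimulus(n = 12, seed = 59)
  cfg <- desk_sim(input_shaping = shaping_tilt(-6, 4000))
  k <- 0
  src <- function(s) {
    k <<- k + 1
    c2 <- cfg; c2$seed <- 300 + k
    simulate_recording(s, c2)
  }
  tr <- run_equalization_loop(st, src, max_iter = 4, tol_db = 1,
                              band_mode = "parametric")
  expect_true(tr$converged)
  expect_lte(length(tr$iterations), 5)
  rng <- vapply(tr$iterations, `[[`, numeric(1), "range_db")
  sct <- vapply(tr$iterations, `[[`, numeric(1), "scatter_db")
  expect_lt(rng[length(rng)], 1)
  expect_lt(sct[length(sct)], sct[1])
  # max_iter = 0 returns the initial measurement only
  tr0 <- run_equalization_loop(st, src, max_iter = 0)
  expect_equal(length(tr0$iterations), 1)
  # noiseless loop: inequality strictly decreases until tolerance
  src_nf <- function(s) simulate_recording(s, cfg, noise = FALSE)
  trn <- run_equalization_loop(st, src_nf, max_iter = 4, tol_db = 0.1,
                               band_mode = "parametric")
  rngn <- vapply(trn$iterations, `[[`, numeric(1), "range_db")
  expect_true(all(diff(rngn) < 0))
})

test_that("recorded motion is not a proxy for the effective OHC input", {
  st <- desk_stimulus(n = 10, seed = 60)
  # flat effective input at the bundle, tilted linear vibration path
  cfg <- desk_sim(input_shaping = NULL,
                  linear_path_shaping = shaping_tilt(-6, 4000), seed = 1)
  rec <- simulate_recording(st, cfg, noise = FALSE)
  dp <- correct_combinatorial(measure_dp2(rec))
  eff <- fit_bilinear_levels(dp, band_mode = "parametric")
  prim <- measure_primaries(rec)
  eff_shape <- eff$levels_db - mean(eff$levels_db)
  motion_shape <- prim$magnitude_db - mean(prim$magnitude_db)
  # the retrieved input is flat; the recorded primary motion is not
  expect_lt(diff(range(eff_shape)), 0.5)
  expect_gt(diff(range(motion_shape)), 5)
})

test_that("degenerate retrieval inputs fail loudly", {
  st <- desk_stimulus(n = 6, seed = 61)
  cfg <- desk_sim(c2 = 0, seed = 2) # no rectification -> no DP2s
  dp <- correct_combinatorial(measure_dp2(simulate_recording(st, cfg)))
  expect_error(fit_bilinear_levels(dp), "significant")
  expect_error(fit_primary_phases(dp), "significant")
})
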