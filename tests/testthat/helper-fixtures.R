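# Shared fixtures: desk-scale records (1.2 s, base 10 Hz, 12 x 0.1-s
# Rayleigh segments) keep the suite fast while preserving the coherence
# structure of the full 12-s recordings.

desk_stimulus <- function(n = 12, f_min = 2000, f_max = 8000, seed = 2,
                          level = 60, ...) {
  design_zwuis(design_constraints(
    n_components = n, f_min_hz = f_min, f_max_hz = f_max, seed = seed,
    base_frequency_hz = 10, duration_s = 1.2, level_db_spl = level, ...
  ))
}

desk_sim <- function(...) {
  sim_config(duration_s = 1.2, ...)
}

# Two-tone stimulus of the classic rectification demo: 4600 + 5400 Hz.
two_tone <- function(level = 70, duration_s = 0.05) {
  zwuis_stimulus(c(23, 27), base_frequency_hz = 200, levels_db_spl = level,
                 phases_cycles = 0, duration_s = duration_s)
}

# Independent closed-form oracle for the quadratic-path DP2 spectrum:
# product-to-sum trigonometry on the shaped input, then the analytic filter
# response. Never touches the time-domain simulator.
quad_dp2_oracle <- function(stimulus, config) {
  g <- zwuisdp:::shaping_gain(config$input_shaping,
                              stimulus$component_frequencies_hz)
  a <- 2e-5 * 10^(stimulus$levels_db_spl / 20) * Mod(g)
  ph <- stimulus$phases_cycles + Arg(g) / (2 * pi)
  cat2 <- dp2_catalog(stimulus)
  amp_nl <- config$c2 * a[cat2$parent_k] * a[cat2$parent_m] *
    ifelse(cat2$is_second_harmonic, 0.5, 1)
  ph_nl <- ifelse(cat2$sign == "+",
                  ph[cat2$parent_k] + ph[cat2$parent_m],
                  ph[cat2$parent_k] - ph[cat2$parent_m]) +
    ifelse(config$polarity < 0, 0.5, 0)
  H <- lpf_response(cat2$frequency_hz, config$corner_frequency_hz)
  cat2$amplitude_nm <- config$motile_gain * amp_nl * Mod(H)
  cat2$phase_cycles <- zwuisdp:::wrap_unit(ph_nl + Arg(H) / (2 * pi))
  cat2
}
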