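#' Input-shaping specifications
#'
#' The effective drive at the OHC hair bundles differs from the ear-canal
#' pressure by middle-ear and intracochlear transfer characteristics. The
#' simulator represents this as a per-frequency complex gain applied to each
#' stimulus component before the nonlinearity: flat, a dB-per-octave tilt, or
#' a tabulated gain/phase curve.
#'
#' @param db_per_octave slope of the tilt.
#' @param ref_hz frequency at which the tilt gain is 0 dB.
#' @param gain_db_at_ref gain at `ref_hz` (dB).
#' @param frequencies_hz,gain_db,phase_cycles tabulated transfer (linearly
#'   interpolated in log-frequency for gain, linearly for phase).
#' @return a shaping object usable as `input_shaping` in [sim_config()].
#' @export
shaping_flat <- function(gain_db_at_ref = 0) {
  structure(list(kind = "flat", gain_db = gain_db_at_ref), class = "shaping")
}

#' @rdname shaping_flat
#' @export
shaping_tilt <- function(db_per_octave, ref_hz = 1000, gain_db_at_ref = 0) {
  structure(list(kind = "tilt", db_per_octave = db_per_octave,
                 ref_hz = ref_hz, gain_db = gain_db_at_ref),
            class = "shaping")
}

#' @rdname shaping_flat
#' @export
shaping_table <- function(frequencies_hz, gain_db, phase_cycles = 0) {
  structure(list(kind = "table", frequencies_hz = frequencies_hz,
                 gain_db = gain_db,
                 phase_cycles = rep_len(phase_cycles, length(frequencies_hz))),
            class = "shaping")
}

# evaluate a shaping object as a complex gain at given frequencies
shaping_gain <- function(shaping, frequencies_hz) {
  if (is.null(shaping)) return(rep(1 + 0i, length(frequencies_hz)))
  stopifnot(inherits(shaping, "shaping"))
  switch(shaping$kind,
    flat = rep(complex(modulus = db_to_amp(shaping$gain_db), argument = 0),
               length(frequencies_hz)),
    tilt = {
      g <- shaping$gain_db + shaping$db_per_octave *
        log2(frequencies_hz / shaping$ref_hz)
      complex(modulus = db_to_amp(g), argument = 0)
    },
    table = {
      g <- stats::approx(log(shaping$frequencies_hz), shaping$gain_db,
                         xout = log(frequencies_hz), rule = 2)$y
      ph <- stats::approx(log(shaping$frequencies_hz), shaping$phase_cycles,
                          xout = log(frequencies_hz), rule = 2)$y
      complex(modulus = db_to_amp(g), argument = 2 * pi * ph)
    },
    stop("unknown shaping kind")
  )
}

#' Ground-truth configuration of the synthetic cochlea
#'
#' The synthetic cochlea reproduces the statistical structure the DP2
#' analysis assumes: the stimulus is shaped by `input_shaping`, passes
#' through a memoryless rectifying nonlinearity, the rectified output is
#' low-pass filtered (first order, corner `corner_frequency_hz`) and scaled
#' to displacement, a linear (non-rectified) vibration path is added, and a
#' flat Gaussian displacement noise floor completes the record.
#'
#' @param nonlinearity_kind `"quadratic"` (default; the DP2 analysis is blind
#'   to higher-order structure), `"half_wave"`, or `"boltzmann"`.
#' @param polarity `+1` or `-1`; in vivo rectification is negative-going
#'   (default `-1`), which produces the half-cycle low-frequency phase limit
#'   of the DP2s.
#' @param c1 linear feed-through gain of the nonlinearity (dimensionless).
#' @param c2 quadratic coefficient (1/Pa).
#' @param hw_gain half-wave rectifier gain.
#' @param boltzmann_params list with `slope` (Pa) and `x0` (Pa operating
#'   point) for the two-state saturating curve. The operating point must sit
#'   off the symmetric midpoint (`x0 != 0`) for the curve to rectify: at
#'   `x0 = 0` the transfer is odd and generates no even-order distortion.
#' @param corner_frequency_hz corner of the motile low-pass (default 2500 Hz).
#' @param motile_gain displacement per nonlinearity-output unit (nm).
#' @param linear_path_gain direct vibration path (nm/Pa).
#' @param linear_path_shaping optional shaping of the linear path (its
#'   spectrum need not match the effective OHC input).
#' @param input_shaping shaping of the drive reaching the nonlinearity.
#' @param noise_density_pm_per_rthz one-sided displacement noise floor
#'   (default 30 pm/sqrt(Hz), the in vivo measurement floor).
#' @param sample_rate_hz default 111600 Hz.
#' @param duration_s default 12 s.
#' @param seed integer seed for the noise generator.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(nonlinearity_kind = c("quadratic", "half_wave", "boltzmann"),
                       polarity = -1,
                       c1 = 0,
                       c2 = 1,
                       hw_gain = 1,
                       boltzmann_params = list(slope = 0.02, x0 = 0.02),
                       corner_frequency_hz = 2500,
                       motile_gain = 2500,
                       linear_path_gain = 50,
                       linear_path_shaping = NULL,
                       input_shaping = NULL,
                       noise_density_pm_per_rthz = 30,
                       sample_rate_hz = 111600,
                       duration_s = 12,
                       seed = 1) {
  nonlinearity_kind <- match.arg(nonlinearity_kind)
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  if (corner_frequency_hz <= 0) stop("corner_frequency_hz must be positive")
  if (noise_density_pm_per_rthz < 0) stop("noise density must be >= 0")
  structure(list(
    nonlinearity_kind = nonlinearity_kind, polarity = polarity,
    c1 = c1, c2 = c2, hw_gain = hw_gain,
    boltzmann_params = boltzmann_params,
    corner_frequency_hz = corner_frequency_hz,
    motile_gain = motile_gain,
    linear_path_gain = linear_path_gain,
    linear_path_shaping = linear_path_shaping,
    input_shaping = input_shaping,
    noise_density_pm_per_rthz = noise_density_pm_per_rthz,
    sample_rate_hz = sample_rate_hz, duration_s = duration_s,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Memoryless rectifying nonlinearity
#'
#' Sample-wise transfer applied to the bundle-deflection waveform:
#' quadratic `v = c1*u + polarity*c2*u^2`; half-wave
#' `v = polarity*hw_gain*max(polarity*u, 0)`; Boltzmann, a two-state
#' saturating activation `1/(1+exp(-(u - x0)/slope))` centred on its resting
#' value, signed by `polarity`.
#'
#' @param u numeric input waveform (Pa at the bundle).
#' @param config a [sim_config()].
#' @return numeric waveform.
#' @export
apply_nonlinearity <- function(u, config) {
  stopifnot(inherits(config, "sim_config"), all(is.finite(u)))
  pol <- config$polarity
  switch(config$nonlinearity_kind,
    quadratic = config$c1 * u + pol * config$c2 * u^2,
    half_wave = pol * config$hw_gain * pmax(pol * u, 0),
    boltzmann = {
      s <- config$boltzmann_params$slope
      x0 <- config$boltzmann_params$x0
      act <- function(x) 1 / (1 + exp(-(x - x0) / s))
      pol * (act(pol * u) - act(0))
    },
    stop("unknown nonlinearity kind")
  )
}

#' First-order low-pass filter, exact in the frequency domain
#'
#' Applies `H(f) = 1 / (1 + i f / fc)` bin-wise to the DFT of a coherent
#' record: magnitude `-10*log10(1 + (f/fc)^2)` dB and phase
#' `-atan(f/fc)/(2*pi)` cycles at every analysis frequency, with no start-up
#' transient or group-delay approximation.
#'
#' @param v numeric waveform.
#' @param fc corner frequency (Hz), positive and below Nyquist.
#' @param sample_rate_hz sampling rate.
#' @return filtered waveform.
#' @export
apply_first_order_lpf <- function(v, fc, sample_rate_hz) {
  if (fc <= 0) stop("fc must be positive")
  if (fc >= sample_rate_hz / 2) stop("fc must be below the Nyquist frequency")
  ns <- length(v)
  k <- seq.int(0, ns - 1)
  f <- ifelse(k <= ns / 2, k, k - ns) * sample_rate_hz / ns
  H <- 1 / (1 + 1i * f / fc)
  Re(stats::fft(stats::fft(v) * H, inverse = TRUE)) / ns
}

# closed-form response of the first-order low-pass filter
#' First-order low-pass filter response
#'
#' @param f frequency (Hz).
#' @param fc corner frequency (Hz).
#' @return `lpf_response`: complex gain; `lpf_magnitude_db`: dB magnitude;
#'   `lpf_phase_cycles`: phase in cycles.
#' @export
lpf_response <- function(f, fc) 1 / (1 + 1i * f / fc)

#' @rdname lpf_response
#' @export
lpf_magnitude_db <- function(f, fc) -10 * log10(1 + (f / fc)^2)

#' @rdname lpf_response
#' @export
lpf_phase_cycles <- function(f, fc) -atan(f / fc) / (2 * pi)

#' Simulate a single-point OHC-region displacement record
#'
#' Composes the synthetic cochlea: shaped stimulus -> rectifier -> first-order
#' low-pass -> motile displacement, summed with a linear vibration path and a
#' flat Gaussian noise floor. Returns the record plus a ground-truth ledger
#' holding every parameter and the shaped (effective) input levels and
#' phases, for use in recovery tests.
#'
#' @param stimulus a [zwuis_stimulus()].
#' @param config a [sim_config()]; its `sample_rate_hz`/`duration_s` must
#'   match the stimulus.
#' @param noise override the configured noise (e.g. `FALSE` for a noiseless
#'   run); default uses `config$noise_density_pm_per_rthz`.
#' @return a list of class `ohc_recording` with elements `displacement_nm`,
#'   `sample_rate_hz`, `duration_s`, `stimulus`, `truth`.
#' @export
simulate_recording <- function(stimulus, config, noise = TRUE) {
  stopifnot(inherits(stimulus, "zwuis_stimulus"), inherits(config, "sim_config"))
  if (config$sample_rate_hz != stimulus$sample_rate_hz ||
      config$duration_s != stimulus$duration_s) {
    stop("config and stimulus disagree on sample rate or duration")
  }
  f <- stimulus$component_frequencies_hz
  g_in <- shaping_gain(config$input_shaping, f)
  shaped <- stimulus
  shaped$levels_db_spl <- stimulus$levels_db_spl + amp_to_db(Mod(g_in))
  shaped$phases_cycles <- wrap_unit(stimulus$phases_cycles + Arg(g_in) / (2 * pi))
  u <- synthesize_waveform(shaped)

  g_lin <- shaping_gain(config$linear_path_shaping, f)
  lin_stim <- stimulus
  lin_stim$levels_db_spl <- stimulus$levels_db_spl + amp_to_db(Mod(g_lin))
  lin_stim$phases_cycles <- wrap_unit(stimulus$phases_cycles + Arg(g_lin) / (2 * pi))
  u_lin <- if (identical(config$linear_path_shaping, config$input_shaping)) u else
    synthesize_waveform(lin_stim)

  motile <- config$motile_gain *
    apply_first_order_lpf(apply_nonlinearity(u, config),
                          config$corner_frequency_hz, config$sample_rate_hz)
  d <- config$linear_path_gain * u_lin + motile

  rho_nm <- config$noise_density_pm_per_rthz * 1e-3
  if (isTRUE(noise) && rho_nm > 0) {
    sd_nm <- rho_nm * sqrt(config$sample_rate_hz / 2)
    d <- d + withr::with_seed(config$seed, stats::rnorm(length(d), 0, sd_nm))
  }

  structure(list(
    displacement_nm = d,
    sample_rate_hz = config$sample_rate_hz,
    duration_s = config$duration_s,
    stimulus = stimulus,
    truth = list(
      config = config,
      effective_input_levels_db = shaped$levels_db_spl,
      effective_input_phases_cycles = shaped$phases_cycles,
      linear_path_levels_db = lin_stim$levels_db_spl +
        amp_to_db(2e-5 * config$linear_path_gain), # dB re 1 nm

      corner_frequency_hz = config$corner_frequency_hz,
      polarity = config$polarity
    )
  ), class = "ohc_recording")
}

#' @export
print.ohc_recording <- function(x, ...) {
  cat(sprintf(
    "OHC-region recording: %.4g s at %.4g kHz (%d samples), %d-tone stimulus\n",
    x$duration_s, x$sample_rate_hz / 1000, length(x$displacement_nm),
    length(x$stimulus$multipliers)
  ))
  cat(sprintf("  ground truth: fc = %.4g Hz, polarity %+d, %s nonlinearity\n",
              x$truth$corner_frequency_hz, x$truth$polarity,
              x$truth$config$nonlinearity_kind))
  invisible(x)
}

#' Write a recording as CSV plus a JSON ground-truth ledger
#'
#' @param recording an `ohc_recording`.
#' @param path CSV path (`time_s`, `displacement_nm`); the ledger is written
#'   alongside with extension `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "ohc_recording"))
  t <- seq_along(recording$displacement_nm) / recording$sample_rate_hz
  utils::write.csv(
    data.frame(time_s = t, displacement_nm = recording$displacement_nm),
    path, row.names = FALSE
  )
  truth <- recording$truth
  truth$config <- unclass(truth$config)
  truth$config$input_shaping <- unclass(truth$config$input_shaping)
  truth$config$linear_path_shaping <- unclass(truth$config$linear_path_shaping)
  jsonlite::write_json(truth, sub("\\.csv$", ".truth.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
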