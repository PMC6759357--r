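#' Configuration for a full closed-loop synthetic experiment
#'
#' Bundles every parameter of the design -> simulate -> analyze -> equalize ->
#' fit pipeline. The `scale` factor shortens the record for desk-scale runs
#' while keeping the analysis coherent: duration `12 * scale` s with 12
#' Rayleigh segments and base frequency `1 / scale` Hz.
#'
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param scale duration scale factor (1 = 12-s records, 0.1 = 1.2-s).
#' @param cf_hz characteristic frequency of the synthetic site (default
#'   16000 Hz).
#' @param n_components primaries in the narrow-band stimulus (default 12).
#' @param f_min_hz lower stimulus band edge (default 300 Hz; primaries reach
#'   up to CF/2).
#' @param level_db_spl initial per-component level (default 60 dB SPL).
#' @param corner_frequency_hz ground-truth motile corner (default 2500 Hz).
#' @param input_shaping shaping of the effective OHC input (default a
#'   -4 dB/octave tilt, emulating non-flat middle-ear/propagation transfer).
#' @param noise_density_pm_per_rthz displacement noise floor (default 30).
#' @param max_iter,tol_db,mu equalization-loop settings.
#' @param band_mode filter proxy in the level retrieval (`"octave"` or
#'   `"parametric"`).
#' @param phase_band_mode filter-phase proxy in the phase retrieval; default
#'   `"parametric"`, since piecewise-constant band offsets alias the smooth
#'   filter phase into the per-primary phase estimates and bias the final
#'   joint fit.
#' @param n_segments,alpha spectral-analysis settings.
#' @param phase_weight_db_per_cycle joint-fit weighting scale.
#' @param sim_overrides named list merged into the [sim_config()] call.
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 1, scale = 1, cf_hz = 16000,
                       n_components = 12, f_min_hz = 300,
                       level_db_spl = 60,
                       corner_frequency_hz = 2500,
                       input_shaping = shaping_tilt(-4, ref_hz = 2000),
                       noise_density_pm_per_rthz = 30,
                       max_iter = 4, tol_db = 1, mu = 1,
                       band_mode = "octave",
                       phase_band_mode = "parametric",
                       n_segments = 12, alpha = 0.001,
                       phase_weight_db_per_cycle = 40,
                       sim_overrides = list()) {
  stopifnot(scale > 0, n_segments >= 4)
  structure(list(
    seed = as.integer(seed), scale = scale, cf_hz = cf_hz,
    n_components = n_components, f_min_hz = f_min_hz,
    level_db_spl = level_db_spl,
    corner_frequency_hz = corner_frequency_hz,
    input_shaping = input_shaping,
    noise_density_pm_per_rthz = noise_density_pm_per_rthz,
    max_iter = max_iter, tol_db = tol_db, mu = mu,
    band_mode = band_mode, phase_band_mode = phase_band_mode,
    n_segments = n_segments, alpha = alpha,
    phase_weight_db_per_cycle = phase_weight_db_per_cycle,
    duration_s = 12 * scale,
    base_frequency_hz = 1 / scale,
    sample_rate_hz = 111600,
    sim_overrides = sim_overrides
  ), class = "run_config")
}

# simulator configured from a run_config; presentation index decorrelates
# the noise between stimulus presentations
pipeline_sim_config <- function(config, presentation = 1L) {
  args <- list(
    corner_frequency_hz = config$corner_frequency_hz,
    input_shaping = config$input_shaping,
    noise_density_pm_per_rthz = config$noise_density_pm_per_rthz,
    sample_rate_hz = config$sample_rate_hz,
    duration_s = config$duration_s,
    seed = (config$seed * 1000L + presentation) %% .Machine$integer.max
  )
  args[names(config$sim_overrides)] <- config$sim_overrides
  do.call(sim_config, args)
}

#' Run the full closed-loop experiment on the synthetic cochlea
#'
#' Designs a narrow-band zwuis stimulus (primaries up to CF/2), runs the
#' stimulus-equalization loop against the synthetic cochlea, applies the
#' post-hoc residual-inequality correction, predicts DP2 phases from the
#' retrieved input phases, and jointly fits the first-order low-pass filter.
#' When `out_dir` is given, per-stage artifacts (stimulus JSON, per-iteration
#' level tables, DP2 tables, effective-input report, fit report and model
#' curves) plus a provenance manifest are written under stage-numbered
#' subdirectories.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return a list of class `pipeline_report`: `fit` (the [fit_first_order_lpf()]
#'   result), `corner_frequency_hz`, `explained_variance`,
#'   `octaves_below_cf`, `trajectory`, `effective_input`, `dp2`, `stimulus`,
#'   `truth_corner_frequency_hz`, `config`.
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  constraints <- design_constraints(
    n_components = config$n_components,
    f_min_hz = config$f_min_hz,
    f_max_hz = config$cf_hz / 2,
    cf_hz = config$cf_hz,
    seed = config$seed,
    base_frequency_hz = config$base_frequency_hz,
    duration_s = config$duration_s,
    sample_rate_hz = config$sample_rate_hz,
    level_db_spl = config$level_db_spl
  )
  stimulus <- design_zwuis(constraints)

  presentation <- 0L
  source_fn <- function(stim) {
    presentation <<- presentation + 1L
    simulate_recording(stim, pipeline_sim_config(config, presentation))
  }
  trajectory <- run_equalization_loop(
    stimulus, source_fn, max_iter = config$max_iter, tol_db = config$tol_db,
    mu = config$mu, cf_hz = config$cf_hz, n_segments = config$n_segments,
    alpha = config$alpha, band_mode = config$band_mode
  )
  last <- trajectory$iterations[[length(trajectory$iterations)]]
  dp2 <- last$dp2
  eff <- last$effective_input
  phases <- fit_primary_phases(dp2, polarity = -1,
                               band_mode = config$phase_band_mode)
  eff$phases_cycles <- phases$phases_cycles

  dp2 <- posthoc_input_correction(dp2, eff)
  dp2 <- predict_phase(dp2, input_phases_cycles = eff$phases_cycles,
                       polarity = +1) # raw residuals; fit resolves the offset
  sig <- dp2[dp2$significant & !dp2$phase_excluded, , drop = FALSE]
  fit <- fit_first_order_lpf(
    sig$frequency_hz, sig$magnitude_db_equalized, sig$phase_residual_cycles,
    weights = pmin(sig$snr, 1e6)^2,
    phase_weight_db_per_cycle = config$phase_weight_db_per_cycle
  )
  report_tbl <- corner_vs_cf_report(list(fit), config$cf_hz)

  truth_fc <- pipeline_sim_config(config)$corner_frequency_hz
  report <- structure(list(
    fit = fit,
    corner_frequency_hz = fit$corner_frequency_hz,
    explained_variance = fit$explained_variance,
    octaves_below_cf = report_tbl$octaves_below_cf[1],
    trajectory = trajectory,
    effective_input = eff,
    dp2 = dp2,
    stimulus = trajectory$iterations[[length(trajectory$iterations)]]$stimulus,
    truth_corner_frequency_hz = truth_fc,
    config = config
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_artifacts(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("closed-loop OHC corner-frequency pipeline\n")
  cat(sprintf("  fitted corner %.4g Hz (truth %.4g Hz), EV %.1f%%\n",
              x$corner_frequency_hz, x$truth_corner_frequency_hz,
              100 * x$explained_variance))
  cat(sprintf("  %.2f octaves below the %.3g-kHz CF\n",
              x$octaves_below_cf, x$config$cf_hz / 1000))
  print(x$trajectory)
  invisible(x)
}

write_pipeline_artifacts <- function(report, out_dir) {
  dirs <- file.path(out_dir, c("01_design", "02_equalization", "03_dp2",
                               "04_effective_input", "05_fit"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_stimulus_json(report$stimulus, file.path(dirs[1], "stimulus.json"))
  tr <- report$trajectory
  traj_tbl <- data.frame(
    iteration = seq_along(tr$iterations) - 1L,
    input_range_db = vapply(tr$iterations, `[[`, numeric(1), "range_db"),
    dp2_scatter_db = vapply(tr$iterations, `[[`, numeric(1), "scatter_db")
  )
  utils::write.csv(traj_tbl, file.path(dirs[2], "trajectory.csv"),
                   row.names = FALSE)
  for (i in seq_along(tr$iterations)) {
    utils::write.csv(
      as.data.frame(tr$iterations[[i]]$stimulus),
      file.path(dirs[2], sprintf("iteration_%02d_stimulus.csv", i - 1L)),
      row.names = FALSE
    )
  }
  write_dp2_csv(report$dp2, file.path(dirs[3], "dp2_table.csv"))
  eff <- report$effective_input
  jsonlite::write_json(eff[c("levels_db", "level_uncertainties_db",
                             "phases_cycles", "band_offsets_db",
                             "reference_convention", "n_dp2_used",
                             "residual_rms_db")],
                       file.path(dirs[4], "effective_input.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  fit <- report$fit
  jsonlite::write_json(list(
    corner_frequency_hz = fit$corner_frequency_hz,
    gain_db = fit$gain_db,
    polarity_offset_cycles = fit$polarity_offset_cycles,
    explained_variance = fit$explained_variance,
    explained_variance_magnitude = fit$explained_variance_magnitude,
    n_points = fit$n_points,
    weighting_spec = fit$weighting_spec,
    octaves_below_cf = report$octaves_below_cf,
    truth_corner_frequency_hz = report$truth_corner_frequency_hz
  ), file.path(dirs[5], "fit.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(lpf_fit_curve(fit), file.path(dirs[5], "model_curve.csv"),
                   row.names = FALSE)

  cfg_path <- file.path(out_dir, "config.json")
  cfg <- report$config
  cfg$input_shaping <- unclass(cfg$input_shaping)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(
    package = "zwuisdp",
    version = tryCatch(as.character(utils::packageVersion("zwuisdp")),
                       error = function(e) "dev"),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = report$config$seed,
    stages = basename(dirs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
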