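#' Post-hoc correction of DP2 magnitudes for residual input inequality
#'
#' After equalization the effective input is flat only to within the loop
#' tolerance. The bilinear model predicts that a DP2 with parents `k, m`
#' carries the residual inequality `(L_k - mean(L)) + (L_m - mean(L))`;
#' subtracting it collapses the remaining scatter onto the filter-only trend.
#' Phases are untouched: companion phases are unaffected by amplitude
#' inequality.
#'
#' @param dp2set a corrected `dp2_set`.
#' @param effective_input an [fit_bilinear_levels()] result (its `levels_db`
#'   supply `L_k`).
#' @return the set with column `magnitude_db_equalized`; entries with a
#'   missing parent level are dropped.
#' @export
posthoc_input_correction <- function(dp2set, effective_input) {
  stopifnot(inherits(dp2set, "dp2_set"),
            inherits(effective_input, "effective_input"))
  dp2set <- correct_combinatorial(dp2set)
  L <- effective_input$levels_db
  dL <- L - mean(L)
  ok <- dp2set$parent_k <= length(L) & dp2set$parent_m <= length(L) &
    !is.na(dL[dp2set$parent_k]) & !is.na(dL[dp2set$parent_m])
  out <- dp2set[ok, , drop = FALSE]
  out$magnitude_db_equalized <- out$magnitude_db_corrected -
    dL[out$parent_k] - dL[out$parent_m]
  attr(out, "stimulus") <- attr(dp2set, "stimulus")
  attr(out, "corrected") <- TRUE
  class(out) <- class(dp2set)
  out
}

#' Jointly fit a first-order low-pass filter to DP2 magnitudes and phases
#'
#' Minimizes the weighted sum of squared magnitude residuals
#' `D_i - (K - 10*log10(1 + (f_i/fc)^2))` and phase residuals
#' `psi_i - (-atan(f_i/fc)/(2*pi))` over the corner frequency `fc` and gain
#' `K`. Phase errors are converted to dB-equivalent units by the weighting
#' scale `s` (default 40 dB/cycle, i.e. 0.025 cycle per dB). The search runs
#' over an octave-spaced grid of corner frequencies (0.25-16 kHz) refined by
#' golden-section optimization of `log2(fc)`; `K` is profiled analytically.
#' With negative-polarity rectification the phase data sit half a cycle away
#' from the filter phase; the fit detects (or is told) this polarity offset
#' and removes it before fitting.
#'
#' @param frequencies_hz DP2 frequencies.
#' @param magnitudes_db (corrected, equalized) DP2 magnitudes, dB re 1 nm.
#' @param phase_residuals_cycles DP2 phase residuals re the primary-phase
#'   prediction; `NULL` for a magnitude-only fit.
#' @param weights per-point weights (recycled).
#' @param phase_weight_db_per_cycle the scale `s` (default 40).
#' @param polarity_offset `"auto"` (default), `"none"` (0) or `"half"`
#'   (0.5 cycles).
#' @param fc_grid_hz multi-start grid.
#' @return an object of class `lpf_fit` with corner frequency, gain,
#'   polarity offset, joint and magnitude-only explained variance, number of
#'   points, weighting, and a parameter covariance estimate.
#' @export
fit_first_order_lpf <- function(frequencies_hz, magnitudes_db,
                                phase_residuals_cycles = NULL,
                                weights = 1,
                                phase_weight_db_per_cycle = 40,
                                polarity_offset = c("auto", "none", "half"),
                                fc_grid_hz = 2^seq(log2(250), log2(16000), by = 1)) {
  polarity_offset <- match.arg(polarity_offset)
  f <- frequencies_hz
  n <- length(f)
  stopifnot(length(magnitudes_db) == n)
  if (n < 4) stop("need at least 4 points to fit the filter")
  if (log2(max(f) / min(f)) < 1.5) {
    stop("points must span at least 1.5 octaves for an identifiable corner")
  }
  w <- rep_len(weights, n)
  w <- w / mean(w)
  s <- phase_weight_db_per_cycle
  has_phase <- !is.null(phase_residuals_cycles)

  offsets <- switch(polarity_offset, auto = c(0, 0.5), none = 0, half = 0.5)
  if (!has_phase) offsets <- 0

  objective <- function(l2fc, off) {
    fc <- 2^l2fc
    mag_model <- lpf_magnitude_db(f, fc)
    K <- wmean(magnitudes_db - mag_model, w)
    ss <- sum(w * (magnitudes_db - K - mag_model)^2)
    if (has_phase) {
      pr <- wrap_cycles(phase_residuals_cycles - off) - lpf_phase_cycles(f, fc)
      ss <- ss + sum(w * (s * pr)^2)
    }
    ss
  }

  best <- NULL
  for (off in offsets) {
    grid <- sapply(log2(fc_grid_hz), objective, off = off)
    i0 <- which.min(grid)
    lo <- log2(fc_grid_hz[max(1, i0 - 1)])
    hi <- log2(fc_grid_hz[min(length(fc_grid_hz), i0 + 1)])
    opt <- stats::optimize(objective, lower = lo, upper = hi, off = off,
                           tol = 1e-10)
    if (is.null(best) || opt$objective < best$ss) {
      best <- list(l2fc = opt$minimum, ss = opt$objective, off = off)
    }
  }
  fc <- 2^best$l2fc
  if (best$ss > 0 && abs(best$l2fc - log2(min(fc_grid_hz))) < 1e-6) {
    warning("corner frequency pinned at the lower search bound; objective may be flat")
  }
  mag_model <- lpf_magnitude_db(f, fc)
  K <- wmean(magnitudes_db - mag_model, w)
  mag_res <- magnitudes_db - K - mag_model

  # explained variance: joint (weighted stacked residuals, block-wise null
  # model = weighted mean) and magnitude-only
  ss_res_mag <- sum(w * mag_res^2)
  ss_tot_mag <- sum(w * (magnitudes_db - wmean(magnitudes_db, w))^2)
  ev_mag <- 1 - ss_res_mag / ss_tot_mag
  if (has_phase) {
    ph <- wrap_cycles(phase_residuals_cycles - best$off)
    ph_res <- ph - lpf_phase_cycles(f, fc)
    ss_res <- ss_res_mag + sum(w * (s * ph_res)^2)
    ss_tot <- ss_tot_mag + sum(w * (s * (ph - wmean(ph, w)))^2)
    ev_joint <- 1 - ss_res / ss_tot
    npts <- 2L * n
  } else {
    ph_res <- NULL
    ev_joint <- ev_mag
    npts <- n
  }

  # covariance of (log2 fc, K) from the local curvature of the weighted SS
  dof <- max(1, npts - 2L)
  sigma2 <- best$ss / dof
  h <- 1e-4
  d2 <- (objective(best$l2fc + h, best$off) - 2 * best$ss +
           objective(best$l2fc - h, best$off)) / h^2
  var_l2fc <- if (is.finite(d2) && d2 > 0) 2 * sigma2 / d2 else NA_real_
  var_K <- sigma2 / sum(w)
  covar <- matrix(c(var_l2fc, 0, 0, var_K), 2, 2,
                  dimnames = list(c("log2_fc", "K_db"), c("log2_fc", "K_db")))

  structure(list(
    corner_frequency_hz = fc,
    gain_db = K,
    polarity_offset_cycles = best$off,
    explained_variance = ev_joint,
    explained_variance_magnitude = ev_mag,
    n_points = n,
    weighting_spec = sprintf("phase scale %g dB/cycle; %s weights",
                             s, if (length(unique(w)) == 1) "equal" else "custom"),
    phase_weight_db_per_cycle = s,
    covariance = covar,
    magnitude_residuals_db = mag_res,
    phase_residuals_cycles_fit = ph_res,
    frequencies_hz = f
  ), class = "lpf_fit")
}

#' @export
print.lpf_fit <- function(x, ...) {
  cat(sprintf("first-order low-pass fit: fc = %.4g Hz, K = %.3g dB re 1 nm\n",
              x$corner_frequency_hz, x$gain_db))
  cat(sprintf("  polarity offset %.1f cycles; EV %.1f%% joint, %.1f%% magnitude-only; %d points\n",
              x$polarity_offset_cycles, 100 * x$explained_variance,
              100 * x$explained_variance_magnitude, x$n_points))
  invisible(x)
}

#' Evaluate the fitted filter model on a frequency grid
#'
#' Plot-ready table of data and model curves.
#'
#' @param fit an `lpf_fit`.
#' @param frequencies_hz evaluation grid (default: 200 log-spaced points over
#'   the fitted range).
#' @return data.frame with `frequency_hz`, `magnitude_db` (model, including
#'   gain), `phase_cycles` (model, including polarity offset).
#' @export
lpf_fit_curve <- function(fit, frequencies_hz = NULL) {
  stopifnot(inherits(fit, "lpf_fit"))
  f <- frequencies_hz %||%
    2^seq(log2(min(fit$frequencies_hz)), log2(max(fit$frequencies_hz)),
          length.out = 200)
  data.frame(
    frequency_hz = f,
    magnitude_db = fit$gain_db + lpf_magnitude_db(f, fit$corner_frequency_hz),
    phase_cycles = fit$polarity_offset_cycles +
      lpf_phase_cycles(f, fit$corner_frequency_hz)
  )
}

#' Corner frequency versus characteristic frequency report
#'
#' For each recording, the octave distance `log2(CF / fc)` between the
#' characteristic frequency and the fitted motile corner frequency, with the
#' cohort mean and standard deviation.
#'
#' @param fits a list of `lpf_fit` objects (or numeric corner frequencies).
#' @param cf_hz characteristic frequencies, one per fit.
#' @return data.frame with `cf_hz`, `corner_frequency_hz`,
#'   `octaves_below_cf`; mean and SD attached as attributes
#'   `mean_octaves`, `sd_octaves`.
#' @export
corner_vs_cf_report <- function(fits, cf_hz) {
  fc <- if (is.numeric(fits)) fits else
    vapply(fits, function(x) x$corner_frequency_hz, numeric(1))
  stopifnot(length(fc) == length(cf_hz), length(fc) >= 1)
  oct <- log2(cf_hz / fc)
  out <- data.frame(cf_hz = cf_hz, corner_frequency_hz = fc,
                    octaves_below_cf = oct)
  attr(out, "mean_octaves") <- mean(oct)
  attr(out, "sd_octaves") <- if (length(oct) > 1) stats::sd(oct) else NA_real_
  out
}
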