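# Octave-wide DP2-frequency bands used as a nonparametric filter proxy.
# Returns an integer band index per frequency, 1 = lowest occupied band.
dp_band_index <- function(f_hz, band_octaves = 1) {
  b <- floor(log2(f_hz / min(f_hz)) / band_octaves)
  match(b, sort(unique(b)))
}

#' Within-band scatter of corrected DP2 magnitudes
#'
#' Root-mean-square deviation of the corrected DP2 magnitudes from their
#' band means; the quantity the stimulus-equalization loop drives down.
#'
#' @param dp2set a corrected `dp2_set` (significant entries are used).
#' @param band_octaves band width in octaves.
#' @return scalar RMS scatter in dB.
#' @export
dp2_scatter_db <- function(dp2set, band_octaves = 1) {
  d <- dp2set[dp2set$significant, , drop = FALSE]
  stopifnot(nrow(d) > 0, !is.null(d$magnitude_db_corrected))
  b <- dp_band_index(d$frequency_hz, band_octaves)
  dev <- d$magnitude_db_corrected - stats::ave(d$magnitude_db_corrected, b)
  sqrt(mean(dev^2))
}

#' Retrieve the effective OHC input levels from DP2 magnitudes
#'
#' A quadratic (rectifying) nonlinearity makes every DP2 amplitude
#' proportional to the product of its two parent amplitudes, i.e. additive in
#' dB: `D_km = C + L_k + L_m + F(f_km)`, where `L_k` are the effective
#' per-primary input levels and `F` is the transfer (low-pass filter) between
#' rectifier and recorded displacement. The model is solved by weighted
#' linear least squares over the Rayleigh-significant, combinatorially
#' corrected DP2s. Identifiability anchors: `mean(L_k)` equals `anchor_db`
#' (default: mean stimulus level) and `F = 0` in the lowest band
#' (`band_mode = "octave"`); in parametric mode `F` is the first-order
#' low-pass magnitude with its corner fitted jointly.
#'
#' @param dp2set a `dp2_set`; combinatorial correction is applied if absent.
#' @param anchor_db level anchor in dB (default mean stimulus level).
#' @param band_mode `"octave"` (nonparametric band offsets, default) or
#'   `"parametric"` (first-order low-pass magnitude).
#' @param band_octaves band width for `"octave"` mode.
#' @param weights `"snr"` (inverse-variance from the segment-phasor SNR,
#'   default) or `"equal"`.
#' @param fc_grid_hz corner-frequency search grid for parametric mode.
#' @return an object of class `effective_input`.
#' @export
fit_bilinear_levels <- function(dp2set,
                                anchor_db = NULL,
                                band_mode = c("octave", "parametric"),
                                band_octaves = 1,
                                weights = c("snr", "equal"),
                                fc_grid_hz = 2^seq(log2(250), log2(16000), by = 0.1)) {
  band_mode <- match.arg(band_mode)
  weights <- match.arg(weights)
  stopifnot(inherits(dp2set, "dp2_set"))
  dp2set <- correct_combinatorial(dp2set)
  stim <- attr(dp2set, "stimulus")
  N <- length(stim$multipliers)
  d <- dp2set[dp2set$significant & is.finite(dp2set$magnitude_db_corrected), ,
              drop = FALSE]
  if (nrow(d) == 0L) stop("no Rayleigh-significant DP2s: cannot retrieve the effective input")
  anchor_db <- anchor_db %||% mean(stim$levels_db_spl)
  w <- if (weights == "snr") pmin(d$snr, 1e6)^2 else rep(1, nrow(d))
  w <- w / mean(w)

  # parent incidence: row i has +1 at k and +1 at m (2 at k for harmonics)
  P <- matrix(0, nrow(d), N)
  for (i in seq_len(nrow(d))) {
    P[i, d$parent_k[i]] <- P[i, d$parent_k[i]] + 1
    P[i, d$parent_m[i]] <- P[i, d$parent_m[i]] + 1
  }
  support <- colSums(P > 0)
  Z <- stats::contr.sum(N) # L = anchor + Z %*% gamma enforces mean(L) = anchor
  y <- d$magnitude_db_corrected - 2 * anchor_db

  solve_given_F <- function(Fvals, extra_cols = NULL, extra_names = NULL) {
    X <- cbind(`(C)` = 1, P %*% Z, extra_cols)
    colnames(X) <- c("(C)", paste0("g", seq_len(N - 1)), extra_names)
    fit <- stats::lm.wfit(X, y - Fvals, w)
    fit
  }

  if (band_mode == "octave") {
    b <- dp_band_index(d$frequency_hz, band_octaves)
    B <- max(b)
    Bm <- if (B > 1) {
      m <- matrix(0, nrow(d), B - 1)
      for (j in 2:B) m[b == j, j - 1] <- 1
      m
    } else NULL
    fit <- solve_given_F(0, Bm, if (B > 1) paste0("F", 2:B) else NULL)
    fc_hat <- NULL
    co <- fit$coefficients
    band_offsets <- c(0, if (B > 1) co[paste0("F", 2:B)] else NULL)
    names(band_offsets) <- paste0("band", seq_len(B))
  } else {
    sse_for <- function(fc) {
      fit <- solve_given_F(lpf_magnitude_db(d$frequency_hz, fc))
      sum(w * fit$residuals^2)
    }
    sses <- vapply(fc_grid_hz, sse_for, numeric(1))
    i0 <- which.min(sses)
    lo <- fc_grid_hz[max(1, i0 - 1)]; hi <- fc_grid_hz[min(length(fc_grid_hz), i0 + 1)]
    fc_hat <- stats::optimize(function(l2) sse_for(2^l2),
                              lower = log2(lo), upper = log2(hi))$minimum
    fc_hat <- 2^fc_hat
    fit <- solve_given_F(lpf_magnitude_db(d$frequency_hz, fc_hat))
    co <- fit$coefficients
    band_offsets <- NULL
  }
  gamma <- co[paste0("g", seq_len(N - 1))]
  if (anyNA(gamma)) {
    bad <- which(support == 0)
    stop(sprintf("rank-deficient bilinear system; unresolvable primaries: %s",
                 paste(bad, collapse = ", ")))
  }
  L <- as.numeric(anchor_db + Z %*% gamma)
  res <- fit$residuals
  dof <- max(1, nrow(d) - fit$rank)
  sigma2 <- sum(w * res^2) / dof
  # covariance of coefficients from the weighted QR (R'R = X'WX)
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  covb <- matrix(NA_real_, length(co), length(co))
  Ri <- tryCatch(solve(R[seq_len(fit$rank), seq_len(fit$rank)]), error = function(e) NULL)
  if (!is.null(Ri)) covb[piv, piv] <- sigma2 * tcrossprod(Ri)
  gidx <- match(paste0("g", seq_len(N - 1)), colnames(fit$qr$qr))
  se_L <- rep(NA_real_, N)
  if (!anyNA(gidx) && !is.null(Ri)) {
    cg <- covb[gidx, gidx, drop = FALSE]
    if (!anyNA(cg)) se_L <- sqrt(pmax(0, diag(Z %*% cg %*% t(Z))))
  }

  structure(list(
    levels_db = L,
    level_uncertainties_db = se_L,
    phases_cycles = rep(NA_real_, N),
    band_offsets_db = band_offsets,
    corner_frequency_hz = fc_hat,
    gain_db = unname(co["(C)"]),
    reference_convention = sprintf(
      "mean(L) anchored at %.3g dB; %s", anchor_db,
      if (band_mode == "octave") "F(lowest band) = 0" else
        "F = first-order low-pass magnitude (fitted corner)"),
    anchor_db = anchor_db,
    n_dp2_used = nrow(d),
    support = support,
    underdetermined = support < 2,
    residual_rms_db = sqrt(mean(res^2)),
    band_mode = band_mode
  ), class = "effective_input")
}

#' @export
print.effective_input <- function(x, ...) {
  cat(sprintf("effective OHC input from %d DP2s (%s bands)\n",
              x$n_dp2_used, x$band_mode))
  cat(sprintf("  levels %.2f to %.2f dB (range %.2f dB), residual RMS %.2f dB\n",
              min(x$levels_db), max(x$levels_db),
              max(x$levels_db) - min(x$levels_db), x$residual_rms_db))
  cat(" ", x$reference_convention, "\n")
  if (any(x$underdetermined)) {
    cat(sprintf("  WARNING: primaries %s supported by < 2 DP2s\n",
                paste(which(x$underdetermined), collapse = ", ")))
  }
  invisible(x)
}

#' Retrieve per-primary phases of the effective OHC input
#'
#' DP2 phases obey `psi_km = phi_k +/- phi_m + Psi(f_km) + rho` (plus half a
#' cycle for negative-polarity rectification). The fit initializes the
#' primary phases at the stimulus phases, re-centres the wrapped residuals by
#' their circular mean to avoid wrap discontinuities, and solves for phase
#' corrections, band phase offsets (or a parametric first-order low-pass
#' phase) and a constant by weighted least squares.
#'
#' @inheritParams fit_bilinear_levels
#' @param polarity rectifier polarity (default `-1`).
#' @param init_phases_cycles starting phases (default: stimulus phases).
#' @return list with `phases_cycles`, `band_phase_offsets_cycles`,
#'   `corner_frequency_hz` (parametric mode), `rho_cycles`, `n_used`,
#'   `residual_rms_cycles`, `low_confidence`.
#' @export
fit_primary_phases <- function(dp2set, polarity = -1,
                               init_phases_cycles = NULL,
                               band_mode = c("octave", "parametric"),
                               band_octaves = 1,
                               weights = c("snr", "equal"),
                               fc_grid_hz = 2^seq(log2(250), log2(16000), by = 0.1)) {
  band_mode <- match.arg(band_mode)
  weights <- match.arg(weights)
  stopifnot(inherits(dp2set, "dp2_set"))
  stim <- attr(dp2set, "stimulus")
  N <- length(stim$multipliers)
  phi0 <- init_phases_cycles %||% stim$phases_cycles
  d <- dp2set[dp2set$significant, , drop = FALSE]
  if (nrow(d) == 0L) stop("no Rayleigh-significant DP2s: cannot retrieve input phases")
  w <- if (weights == "snr") pmin(d$snr, 1e6)^2 else rep(1, nrow(d))
  w <- w / mean(w)
  sgn <- ifelse(d$sign == "+", 1, -1)
  pred0 <- phi0[d$parent_k] + sgn * phi0[d$parent_m] +
    if (polarity < 0) 0.5 else 0
  r <- wrap_cycles(d$phase_cycles - pred0)
  rho0 <- Arg(sum(w * exp(2i * pi * r))) / (2 * pi)
  r <- wrap_cycles(r - rho0)

  # incidence of phase corrections: +1 at k, +/-1 at m (2 at k for harmonics)
  P <- matrix(0, nrow(d), N)
  for (i in seq_len(nrow(d))) {
    P[i, d$parent_k[i]] <- P[i, d$parent_k[i]] + 1
    P[i, d$parent_m[i]] <- P[i, d$parent_m[i]] + sgn[i]
  }
  if (band_mode == "octave") {
    b <- dp_band_index(d$frequency_hz, band_octaves)
    B <- max(b)
    Bm <- if (B > 1) {
      m <- matrix(0, nrow(d), B - 1)
      for (j in 2:B) m[b == j, j - 1] <- 1
      m
    } else NULL
    X <- cbind(`(rho)` = 1, P, Bm)
    colnames(X) <- c("(rho)", paste0("p", seq_len(N)),
                     if (B > 1) paste0("Psi", 2:B) else NULL)
    fit <- stats::lm.wfit(X, r, w)
    co <- fit$coefficients
    band_ph <- c(0, if (B > 1) co[paste0("Psi", 2:B)] else NULL)
    fc_hat <- NULL
  } else {
    X0 <- cbind(`(rho)` = 1, P)
    colnames(X0) <- c("(rho)", paste0("p", seq_len(N)))
    sse_for <- function(fc) {
      fit <- stats::lm.wfit(X0, r - lpf_phase_cycles(d$frequency_hz, fc), w)
      sum(w * fit$residuals^2)
    }
    sses <- vapply(fc_grid_hz, sse_for, numeric(1))
    i0 <- which.min(sses)
    lo <- fc_grid_hz[max(1, i0 - 1)]; hi <- fc_grid_hz[min(length(fc_grid_hz), i0 + 1)]
    fc_hat <- 2^stats::optimize(function(l2) sse_for(2^l2),
                                lower = log2(lo), upper = log2(hi))$minimum
    fit <- stats::lm.wfit(X0, r - lpf_phase_cycles(d$frequency_hz, fc_hat), w)
    co <- fit$coefficients
    band_ph <- NULL
  }
  dphi <- co[paste0("p", seq_len(N))]
  low_conf <- is.na(dphi)
  dphi[is.na(dphi)] <- 0
  res_rms <- sqrt(mean(fit$residuals^2))
  list(
    phases_cycles = wrap_unit(phi0 + dphi),
    band_phase_offsets_cycles = band_ph,
    corner_frequency_hz = fc_hat,
    rho_cycles = wrap_cycles(rho0 + unname(co["(rho)"])),
    n_used = nrow(d),
    residual_rms_cycles = res_rms,
    low_confidence = low_conf | res_rms > 0.1
  )
}

#' One stimulus-equalization step
#'
#' Subtracts the retrieved effective-input inequality from the stimulus
#' levels (damped by `mu`), then renormalizes so the mean level in dB SPL is
#' unchanged. Frequencies and phases are untouched.
#'
#' @param stimulus current [zwuis_stimulus()].
#' @param effective_input an [fit_bilinear_levels()] result.
#' @param mu step gain in `(0, 1]` (default 1).
#' @return the adjusted stimulus.
#' @export
equalization_step <- function(stimulus, effective_input, mu = 1) {
  stopifnot(inherits(stimulus, "zwuis_stimulus"),
            inherits(effective_input, "effective_input"),
            mu > 0, mu <= 1)
  L <- effective_input$levels_db
  newl <- stimulus$levels_db_spl - mu * (L - mean(L))
  newl <- newl - mean(newl) + mean(stimulus$levels_db_spl)
  out <- stimulus
  out$levels_db_spl <- newl
  out
}

#' Run the closed-loop stimulus equalization
#'
#' Iterates measure -> retrieve -> adjust against a recording source (the
#' synthetic cochlea in this package) until the retrieved effective-input
#' inequality `max |L_k - mean(L)|` falls below `tol_db` or `max_iter`
#' adjustments have been made. If the inequality grows on two consecutive
#' iterations the step gain is halved with a warning.
#'
#' @param stimulus initial [zwuis_stimulus()].
#' @param source function taking a stimulus and returning an
#'   `ohc_recording` (or bare waveform at the stimulus sample rate).
#' @param max_iter maximum number of stimulus adjustments (default 4).
#' @param tol_db stop when `max |L_k - mean(L)| < tol_db` (default 1).
#' @param mu initial step gain.
#' @param cf_hz optional CF for band-limiting the DP2s used in the fit.
#' @param n_segments,alpha analysis settings.
#' @param ... passed to [fit_bilinear_levels()].
#' @return a list of class `equalization_trajectory`: per-iteration entries
#'   `(stimulus, dp2, effective_input, range_db, scatter_db)` plus
#'   `converged`.
#' @export
run_equalization_loop <- function(stimulus, source, max_iter = 4, tol_db = 1,
                                  mu = 1, cf_hz = NULL, n_segments = 12,
                                  alpha = 0.001, ...) {
  iters <- list()
  stim <- stimulus
  prev_range <- Inf
  grew <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter + 1L)) {
    rec <- source(stim)
    dp <- measure_dp2(rec, stimulus = stim,
                      sample_rate_hz = if (inherits(rec, "ohc_recording"))
                        NULL else stim$sample_rate_hz,
                      n_segments = n_segments, alpha = alpha)
    dp <- correct_combinatorial(dp)
    if (!is.null(cf_hz)) dp <- apply_band_limit(dp, cf_hz)
    eff <- fit_bilinear_levels(dp, ...)
    range_db <- max(abs(eff$levels_db - mean(eff$levels_db)))
    iters[[it]] <- list(stimulus = stim, dp2 = dp, effective_input = eff,
                        range_db = range_db,
                        scatter_db = dp2_scatter_db(dp))
    if (range_db < tol_db) { converged <- TRUE; break }
    if (it == max_iter + 1L) break
    if (range_db > prev_range) grew <- grew + 1L else grew <- 0L
    if (grew >= 2L) {
      mu <- mu / 2
      warning(sprintf("equalization diverging; step gain halved to %.3g", mu))
      grew <- 0L
    }
    prev_range <- range_db
    stim <- equalization_step(stim, eff, mu = mu)
  }
  structure(list(iterations = iters, converged = converged,
                 tol_db = tol_db, final_mu = mu),
            class = "equalization_trajectory")
}

#' @export
print.equalization_trajectory <- function(x, ...) {
  rng <- vapply(x$iterations, `[[`, numeric(1), "range_db")
  sct <- vapply(x$iterations, `[[`, numeric(1), "scatter_db")
  cat(sprintf("equalization loop: %d measurement(s), %s (tol %.3g dB)\n",
              length(x$iterations),
              if (x$converged) "converged" else "not converged", x$tol_db))
  cat("  input inequality (dB):", paste(sprintf("%.2f", rng), collapse = " -> "), "\n")
  cat("  DP2 scatter (dB):     ", paste(sprintf("%.2f", sct), collapse = " -> "), "\n")
  invisible(x)
}
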