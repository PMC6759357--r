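#' Catalogue the DP2 frequencies of a zwuis stimulus
#'
#' Rectifying an `N`-component zwuis stimulus generates `N^2` distinct DP2
#' components at `f_k + f_m` (k >= m, second harmonics included) and
#' `f_k - f_m` (k > m), each attributable to a unique parent pair when the
#' stimulus carries a PASS uniqueness certificate.
#'
#' @param stimulus a [zwuis_stimulus()].
#' @param nyquist_guard drop DP2s at or above the Nyquist frequency.
#' @return a data.frame with columns `parent_k`, `parent_m` (`k >= m`),
#'   `sign` (`"+"` or `"-"`), `multiple`, `frequency_hz`,
#'   `is_second_harmonic`.
#' @export
dp2_catalog <- function(stimulus, nyquist_guard = TRUE) {
  stopifnot(inherits(stimulus, "zwuis_stimulus"))
  n <- stimulus$multipliers
  e <- enumerate_dp_frequencies(n, 2)
  # enumerate uses ascending (i1 <= i2); express as parent_k >= parent_m
  harm <- is.na(e$i2)
  k <- ifelse(harm, e$i1, e$i2)
  m <- ifelse(harm, e$i1, e$i1)
  sgn <- ifelse(harm | (e$c1 > 0 & e$c2 > 0), "+", "-")
  out <- data.frame(
    parent_k = k, parent_m = m, sign = sgn, multiple = e$multiple,
    frequency_hz = e$multiple * stimulus$base_frequency_hz,
    is_second_harmonic = harm
  )
  if (nyquist_guard) {
    keep <- out$frequency_hz < stimulus$sample_rate_hz / 2
    if (!all(keep)) {
      warning(sprintf("%d DP2 frequencies at/above Nyquist dropped", sum(!keep)))
      out <- out[keep, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Attribute a distortion-product frequency to its parent primaries
#'
#' @param dp_frequency_hz frequency to attribute.
#' @param stimulus a [zwuis_stimulus()] whose uniqueness certificate passes.
#' @return a list `(parent_k, parent_m, sign, is_second_harmonic)`.
#' @export
attribute_parents <- function(dp_frequency_hz, stimulus) {
  cat2 <- dp2_catalog(stimulus, nyquist_guard = FALSE)
  mult <- dp_frequency_hz / stimulus$base_frequency_hz
  if (abs(mult - round(mult)) > 1e-6) {
    stop(sprintf("%g Hz is not an integer multiple of the base frequency", dp_frequency_hz))
  }
  hit <- which(cat2$multiple == round(mult))
  if (length(hit) == 0L) {
    stop(sprintf("%g Hz is not a DP2 of this stimulus", dp_frequency_hz))
  }
  stopifnot(length(hit) == 1L) # impossible under a PASS certificate
  as.list(cat2[hit, c("parent_k", "parent_m", "sign", "is_second_harmonic")])
}

#' Measure the DP2 spectrum of a recording
#'
#' Runs [component_spectrum()] at every DP2 frequency of the stimulus and
#' merges the result with the catalogue.
#'
#' @param record an `ohc_recording` or a numeric waveform.
#' @param stimulus the [zwuis_stimulus()] that evoked the record (taken from
#'   the recording when omitted).
#' @param sample_rate_hz required when `record` is a bare waveform.
#' @param n_segments,alpha,exact passed to [component_spectrum()].
#' @return a `dp2_set`: the catalogue joined with `magnitude_db`
#'   (dB re 1 nm), `phase_cycles`, `rayleigh_R`, `p_value`, `significant`,
#'   `snr`.
#' @export
measure_dp2 <- function(record, stimulus = NULL, sample_rate_hz = NULL,
                        n_segments = 12, alpha = 0.001, exact = FALSE) {
  if (inherits(record, "ohc_recording")) {
    stimulus <- stimulus %||% record$stimulus
    sample_rate_hz <- record$sample_rate_hz
    record <- record$displacement_nm
  }
  stopifnot(inherits(stimulus, "zwuis_stimulus"), !is.null(sample_rate_hz))
  cat2 <- dp2_catalog(stimulus)
  sp <- component_spectrum(record, cat2$frequency_hz, sample_rate_hz,
                           n_segments = n_segments, alpha = alpha,
                           exact = exact)
  out <- cbind(cat2, sp[, c("amplitude_nm", "phase_cycles", "rayleigh_R",
                            "p_value", "significant", "amplitude_se_nm",
                            "snr")])
  out$magnitude_db <- amp_to_db(out$amplitude_nm)
  structure(out, class = c("dp2_set", "data.frame"), stimulus = stimulus,
            corrected = FALSE)
}

#' Measure the primary components of a recording
#'
#' @inheritParams measure_dp2
#' @return a data.frame with one row per primary.
#' @export
measure_primaries <- function(record, stimulus = NULL, sample_rate_hz = NULL,
                              n_segments = 12, alpha = 0.001) {
  if (inherits(record, "ohc_recording")) {
    stimulus <- stimulus %||% record$stimulus
    sample_rate_hz <- record$sample_rate_hz
    record <- record$displacement_nm
  }
  sp <- component_spectrum(record, stimulus$component_frequencies_hz,
                           sample_rate_hz, n_segments = n_segments,
                           alpha = alpha)
  sp$component <- seq_len(nrow(sp))
  sp$magnitude_db <- amp_to_db(sp$amplitude_nm)
  sp
}

#' Correct DP2 magnitudes for the combinatorial second-harmonic deficit
#'
#' Under an even-order (rectifying) nonlinearity the second harmonics of an
#' equal-amplitude complex are a factor 2 (6.02 dB) weaker than mixed DP2s:
#' the cross terms of the squared sum appear twice, the square terms once.
#' The correction adds exactly `20*log10(2)` dB to the harmonics and leaves
#' mixed DP2s untouched; it is idempotent (guarded by an attribute).
#'
#' @param dp2set a `dp2_set` from [measure_dp2()].
#' @return the set with column `magnitude_db_corrected`.
#' @export
correct_combinatorial <- function(dp2set) {
  stopifnot(inherits(dp2set, "dp2_set"))
  if (isTRUE(attr(dp2set, "corrected"))) return(dp2set)
  dp2set$magnitude_db_corrected <- dp2set$magnitude_db +
    ifelse(dp2set$is_second_harmonic, 20 * log10(2), 0)
  attr(dp2set, "corrected") <- TRUE
  dp2set
}

#' Predict DP2 phases from primary phases and form residuals
#'
#' A quadratic nonlinearity maps primary phases to DP2 phases by addition
#' (sum tones, harmonics) or subtraction (difference tones, higher-frequency
#' parent minus lower). Negative-polarity rectification flips the sign of the
#' quadratic term, adding half a cycle to every DP2. The phase residual
#' (measured minus predicted, wrapped to `(-0.5, 0.5]`) then traces the phase
#' of any filter that follows the rectifier.
#'
#' @param dp2set a `dp2_set` with measured `phase_cycles`.
#' @param input_phases_cycles per-primary phases of the effective OHC input;
#'   defaults to the stimulus phases.
#' @param polarity `+1` or `-1` (default `-1`); with `-1`, 0.5 cycles is
#'   added to the prediction.
#' @return the set with columns `predicted_phase_cycles` and
#'   `phase_residual_cycles`; entries with a missing parent phase are flagged
#'   `phase_excluded`.
#' @export
predict_phase <- function(dp2set, input_phases_cycles = NULL, polarity = -1) {
  stopifnot(inherits(dp2set, "dp2_set"))
  stim <- attr(dp2set, "stimulus")
  ph <- input_phases_cycles %||% stim$phases_cycles
  pk <- ph[dp2set$parent_k]
  pm <- ph[dp2set$parent_m]
  pred <- ifelse(dp2set$sign == "+", pk + pm, pk - pm) +
    if (polarity < 0) 0.5 else 0
  dp2set$predicted_phase_cycles <- wrap_unit(pred)
  dp2set$phase_residual_cycles <- wrap_cycles(dp2set$phase_cycles - pred)
  dp2set$phase_excluded <- is.na(pk) | is.na(pm)
  dp2set
}

#' Band-limit a DP2 set to frequencies at or below a fraction of CF
#'
#' Components travelling near their characteristic place suffer interference
#' across distributed generation sites; restricting primaries and DP2s to at
#' most CF/2 (inclusive boundary) keeps propagation fast and magnitudes
#' undistorted.
#'
#' @param dp2set a `dp2_set`.
#' @param cf_hz characteristic frequency of the recording site.
#' @param fraction upper limit as a fraction of CF (default 0.5).
#' @return the filtered set; the number retained is reported as attribute
#'   `n_retained`.
#' @export
apply_band_limit <- function(dp2set, cf_hz, fraction = 0.5) {
  stopifnot(inherits(dp2set, "dp2_set"))
  keep <- dp2set$frequency_hz <= fraction * cf_hz
  out <- dp2set[keep, , drop = FALSE]
  attr(out, "stimulus") <- attr(dp2set, "stimulus")
  attr(out, "corrected") <- attr(dp2set, "corrected")
  attr(out, "n_retained") <- sum(keep)
  class(out) <- class(dp2set)
  out
}

#' Write a DP2 table as CSV
#'
#' @param dp2set a `dp2_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dp2_csv <- function(dp2set, path) {
  utils::write.csv(as.data.frame(dp2set), path, row.names = FALSE)
  invisible(path)
}
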