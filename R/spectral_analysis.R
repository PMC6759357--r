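#' Coherent DFT at stimulus-locked frequencies
#'
#' Extracts the complex amplitude (cosine convention) of a record at
#' frequencies that are exact integer multiples of the reciprocal record
#' duration. A component `a*cos(2*pi*f*t + 2*pi*phi)` is returned as the
#' complex number `a*exp(2i*pi*phi)`. Frequencies that are not bin-aligned
#' are rejected, since off-bin estimates would be contaminated by spectral
#' leakage from neighbouring stimulus components.
#'
#' @param record numeric waveform.
#' @param frequencies_hz frequencies to analyze; each must be an integer
#'   multiple of `sample_rate_hz / length(record)`.
#' @param sample_rate_hz sampling rate.
#' @return complex vector, one element per frequency.
#' @export
coherent_dft <- function(record, frequencies_hz, sample_rate_hz) {
  ns <- length(record)
  dur <- ns / sample_rate_hz
  k <- frequencies_hz * dur
  if (any(abs(k - round(k)) > 1e-6)) {
    bad <- frequencies_hz[abs(k - round(k)) > 1e-6][1]
    stop(sprintf("frequency %g Hz is not an integer multiple of 1/duration (%g Hz): coherent analysis would leak", bad, 1 / dur))
  }
  k <- as.integer(round(k))
  if (any(k < 0) || any(k > ns / 2)) stop("frequencies must lie in [0, Nyquist]")
  X <- stats::fft(record)
  out <- 2 * X[k + 1L] / ns
  out[k == 0L] <- X[1L][k == 0L] / ns # DC has no conjugate partner
  out
}

#' Rayleigh phase-stability test for one spectral component
#'
#' Splits the record into `n_segments` coherent segments, measures the
#' component phase in each, and computes the vector strength
#' `R = |mean_j exp(2i*pi*theta_j)|`. Under the null hypothesis of random
#' phases the large-sample significance is `p = exp(-M R^2)`; with
#' `exact = TRUE` a finite-`M` correction (Greenwood-Durand) is applied.
#'
#' @param record numeric waveform.
#' @param frequency_hz component frequency; must complete an integer number
#'   of cycles per segment.
#' @param n_segments number of segments `M` (at least 4).
#' @param sample_rate_hz sampling rate.
#' @param exact apply the finite-sample correction to the p-value.
#' @return a list with `R` (vector strength), `p`, `n_segments`.
#' @export
rayleigh_test <- function(record, frequency_hz, n_segments,
                          sample_rate_hz, exact = FALSE) {
  z <- segment_phasors(record, frequency_hz, n_segments, sample_rate_hz)
  rayleigh_from_phasors(z, exact = exact)
}

# per-segment complex amplitudes at one or more frequencies; returns a
# matrix (n_segments x n_frequencies)
segment_phasors <- function(record, frequencies_hz, n_segments, sample_rate_hz) {
  if (n_segments < 4) stop("n_segments < 4 is underpowered for a Rayleigh test")
  ns <- length(record)
  if (ns %% n_segments != 0) {
    stop("record length must divide into n_segments equal coherent segments")
  }
  seg_len <- ns %/% n_segments
  seg_dur <- seg_len / sample_rate_hz
  k <- frequencies_hz * seg_dur
  if (any(abs(k - round(k)) > 1e-6)) {
    stop("each frequency must complete an integer number of cycles per segment")
  }
  z <- matrix(0 + 0i, n_segments, length(frequencies_hz))
  for (j in seq_len(n_segments)) {
    seg <- record[((j - 1L) * seg_len + 1L):(j * seg_len)]
    z[j, ] <- coherent_dft(seg, frequencies_hz, sample_rate_hz)
  }
  z
}

rayleigh_from_phasors <- function(z, exact = FALSE) {
  M <- nrow(z)
  th <- Arg(z)
  Rv <- Mod(colMeans(exp(1i * th)))
  Z <- M * Rv^2
  p <- exp(-Z)
  if (exact) {
    p <- p * (1 + (2 * Z - Z^2) / (4 * M) -
                (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * M^2))
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(R = as.numeric(Rv), p = as.numeric(p), n_segments = M)
}

#' Component spectrum with Rayleigh significance
#'
#' Coherent analysis of a displacement record at a set of stimulus-locked
#' frequencies. Amplitude and phase come from the full record; phase
#' stability across `n_segments` coherent segments gives the Rayleigh vector
#' strength, p-value and significance flag. A phasor-domain standard error
#' (segment-to-segment scatter of the complex amplitude) is returned for use
#' as an inverse-variance weight downstream.
#'
#' @param record numeric displacement waveform (nm).
#' @param frequencies_hz bin-aligned analysis frequencies.
#' @param sample_rate_hz sampling rate.
#' @param n_segments Rayleigh segments (default 12; 1-s blocks for the
#'   default 12-s record).
#' @param alpha significance level (default 0.001).
#' @param exact exact small-M Rayleigh correction.
#' @return a data.frame with columns `frequency_hz`, `amplitude_nm`,
#'   `phase_cycles`, `rayleigh_R`, `p_value`, `significant`,
#'   `amplitude_se_nm`, `snr`.
#' @export
component_spectrum <- function(record, frequencies_hz, sample_rate_hz,
                               n_segments = 12, alpha = 0.001,
                               exact = FALSE) {
  z <- segment_phasors(record, frequencies_hz, n_segments, sample_rate_hz)
  zbar <- colMeans(z)
  M <- n_segments
  # complex scatter about the mean -> standard error of the mean phasor
  resid2 <- colSums(Mod(sweep(z, 2, zbar))^2) / (M - 1)
  se <- sqrt(resid2 / M / 2) # per real/imag quadrature
  ray <- rayleigh_from_phasors(z, exact = exact)
  amp <- Mod(zbar)
  data.frame(
    frequency_hz = frequencies_hz,
    amplitude_nm = amp,
    phase_cycles = wrap_unit(Arg(zbar) / (2 * pi)),
    rayleigh_R = ray$R,
    p_value = ray$p,
    significant = ray$p < alpha,
    amplitude_se_nm = se,
    snr = amp / pmax(se, .Machine$double.eps)
  )
}
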