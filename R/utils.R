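#' Wrap phase values to the half-open interval (-0.5, 0.5]
#'
#' Phase residuals are reported in cycles on (-0.5, 0.5], with the boundary
#' mapped to +0.5 so that the half-cycle offset produced by negative-polarity
#' rectification keeps a stable sign at low frequency.
#'
#' @param x numeric vector of phases in cycles.
#' @return numeric vector in (-0.5, 0.5].
#' @export
#' @examples
#' wrap_cycles(c(0.5, -0.5, 1.2, -0.8))
wrap_cycles <- function(x) {
  0.5 - ((0.5 - x) %% 1)
}

#' Wrap phase values to [0, 1)
#' @param x numeric vector of phases in cycles.
#' @return numeric vector in [0, 1).
#' @export
wrap_unit <- function(x) {
  x %% 1
}

# dB <-> linear amplitude
db_to_amp <- function(db) 10^(db / 20)
amp_to_db <- function(a) 20 * log10(a)

# weighted mean that tolerates a scalar weight
wmean <- function(x, w = 1) {
  w <- rep_len(w, length(x))
  sum(w * x) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
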