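#' Construct a zwuis multitone stimulus
#'
#' A zwuis stimulus is a sum of cosines whose frequencies are distinct integer
#' multiples `n_k` of a common base frequency (the reciprocal of one analysis
#' window), chosen so that intermodulation products up to a given order have
#' frequencies that cannot be confused with each other or with the primaries.
#' Every second-order distortion product (DP2) at `f_k + f_m` or `f_k - f_m`
#' can then be attributed to a unique pair of parent primaries.
#'
#' @param multipliers strictly increasing vector of distinct positive integers.
#' @param base_frequency_hz positive scalar; component `k` sits at
#'   `multipliers[k] * base_frequency_hz`.
#' @param levels_db_spl per-component level in dB re 20 uPa (recycled).
#' @param phases_cycles per-component starting phase in `[0, 1)` (recycled).
#' @param duration_s record length; must be an integer number of base periods.
#' @param sample_rate_hz sampling rate (default 111600 Hz).
#' @return an object of class `zwuis_stimulus`.
#' @export
zwuis_stimulus <- function(multipliers,
                           base_frequency_hz = 1,
                           levels_db_spl = 60,
                           phases_cycles = 0,
                           duration_s = 12,
                           sample_rate_hz = 111600) {
  multipliers <- as.integer(multipliers)
  if (any(multipliers <= 0L)) stop("multipliers must be positive integers")
  if (is.unsorted(multipliers, strictly = TRUE)) {
    stop("multipliers must be strictly increasing and distinct")
  }
  if (base_frequency_hz <= 0) stop("base_frequency_hz must be positive")
  freqs <- multipliers * base_frequency_hz
  if (any(freqs >= sample_rate_hz / 2)) {
    stop("all component frequencies must lie below the Nyquist frequency")
  }
  n_base <- duration_s * base_frequency_hz
  if (abs(n_base - round(n_base)) > 1e-9) {
    stop("duration_s must be an integer number of base periods (coherence)")
  }
  x <- list(
    base_frequency_hz = base_frequency_hz,
    multipliers = multipliers,
    component_frequencies_hz = freqs,
    levels_db_spl = rep_len(levels_db_spl, length(multipliers)),
    phases_cycles = wrap_unit(rep_len(phases_cycles, length(multipliers))),
    duration_s = duration_s,
    sample_rate_hz = sample_rate_hz
  )
  class(x) <- "zwuis_stimulus"
  x
}

#' @export
print.zwuis_stimulus <- function(x, ...) {
  n <- length(x$multipliers)
  cat(sprintf(
    "zwuis stimulus: %d components, %.4g-%.4g Hz (base %.4g Hz)\n",
    n, min(x$component_frequencies_hz), max(x$component_frequencies_hz),
    x$base_frequency_hz
  ))
  cat(sprintf(
    "  levels %.3g-%.3g dB SPL, duration %.4g s, fs %.4g Hz\n",
    min(x$levels_db_spl), max(x$levels_db_spl), x$duration_s, x$sample_rate_hz
  ))
  invisible(x)
}

#' @export
as.data.frame.zwuis_stimulus <- function(x, ...) {
  data.frame(
    component = seq_along(x$multipliers),
    multiplier = x$multipliers,
    frequency_hz = x$component_frequencies_hz,
    level_db_spl = x$levels_db_spl,
    phase_cycles = x$phases_cycles
  )
}

#' Design constraints for zwuis stimulus search
#'
#' @param n_components number of primaries (narrow-band stimuli use 10-15,
#'   broad-band characterization uses 43).
#' @param f_min_hz,f_max_hz band edges in Hz. The default lower edge of
#'   300 Hz reflects the "few hundred hertz" convention for narrow-band
#'   stimuli.
#' @param cf_hz optional characteristic frequency of the recording site.
#' @param cf_fraction_limit primaries are kept at or below
#'   `cf_fraction_limit * cf_hz` (default 0.5, i.e. CF/2) so that neither the
#'   primaries nor the DP2s are distorted by traveling-wave interference.
#' @param max_order_unambiguous protect distortion products up to this order
#'   (2 or 3, default 3).
#' @param strict if `TRUE`, require all order-3 combination frequencies to be
#'   mutually distinct and distinct from the order-2 set as well as from the
#'   primaries; the default (`FALSE`) protects the order-2 set fully and
#'   order-3 products against the primaries only, which is what unambiguous
#'   DP2 attribution requires and remains feasible at realistic component
#'   densities.
#' @param seed integer seed for the randomized search.
#' @param max_search_iterations restarts before giving up.
#' @param base_frequency_hz analysis-window reciprocal (default 1 Hz,
#'   i.e. 1-s coherent windows).
#' @param duration_s record duration (integer number of base periods).
#' @param sample_rate_hz sampling rate.
#' @param level_db_spl initial per-component level (components start equal).
#' @param include_edges place components at the exact band edges when
#'   possible, so the stimulus spans the stated band.
#' @return a list of class `design_constraints`.
#' @export
design_constraints <- function(n_components,
                               f_min_hz = 300,
                               f_max_hz,
                               cf_hz = NULL,
                               cf_fraction_limit = 0.5,
                               max_order_unambiguous = 3,
                               strict = FALSE,
                               seed = 1,
                               max_search_iterations = 50,
                               base_frequency_hz = 1,
                               duration_s = 12,
                               sample_rate_hz = 111600,
                               level_db_spl = 60,
                               include_edges = TRUE) {
  if (n_components < 2) stop("n_components must be at least 2")
  if (f_min_hz >= f_max_hz) stop("f_min_hz must be below f_max_hz")
  if (cf_fraction_limit <= 0 || cf_fraction_limit > 1) {
    stop("cf_fraction_limit must lie in (0, 1]")
  }
  if (!max_order_unambiguous %in% c(2, 3)) {
    stop("max_order_unambiguous must be 2 or 3")
  }
  structure(list(
    n_components = as.integer(n_components),
    f_min_hz = f_min_hz, f_max_hz = f_max_hz,
    cf_hz = cf_hz, cf_fraction_limit = cf_fraction_limit,
    max_order_unambiguous = max_order_unambiguous,
    strict = strict, seed = as.integer(seed),
    max_search_iterations = as.integer(max_search_iterations),
    base_frequency_hz = base_frequency_hz,
    duration_s = duration_s,
    sample_rate_hz = sample_rate_hz,
    level_db_spl = level_db_spl,
    include_edges = include_edges
  ), class = "design_constraints")
}

#' Enumerate intermodulation product frequencies with their signatures
#'
#' Lists every non-degenerate combination frequency `|c1 n_i1 + c2 n_i2 +
#' c3 n_i3|` of the given order. Order 2 yields all sums `n_k + n_m`
#' (`k >= m`, second harmonics included) and differences `n_k - n_m`
#' (`k > m`): `N^2` entries for `N` multipliers. Order 3 yields all
#' combinations with integer coefficients summing to 3 in absolute value,
#' excluding self-cancelling (degenerate) terms; the global sign is chosen to
#' make the frequency positive, and exact zeros are dropped.
#'
#' @param multipliers distinct positive integers.
#' @param order 2 or 3.
#' @return a data.frame with columns `i1,i2,i3` (ascending component indices,
#'   `NA` when unused), `c1,c2,c3` (signed integer coefficients), `multiple`
#'   (the combination frequency in units of the base frequency), `order`, and
#'   `signature` (human-readable label).
#' @export
enumerate_dp_frequencies <- function(multipliers, order) {
  if (!order %in% c(2, 3)) stop("order must be 2 or 3")
  n <- as.integer(multipliers)
  if (anyDuplicated(n)) stop("multipliers must be distinct")
  N <- length(n)
  rows <- list()
  if (order == 2) {
    # harmonics 2 n_k
    rows[[1]] <- data.frame(i1 = seq_len(N), i2 = NA_integer_,
                            c1 = 2L, c2 = 0L, multiple = 2L * n)
    if (N >= 2) {
      pr <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE) # i<j pairs
      i <- pr[, 1]; j <- pr[, 2]
      rows[[2]] <- data.frame(i1 = i, i2 = j, c1 = 1L, c2 = 1L,
                              multiple = n[i] + n[j])
      rows[[3]] <- data.frame(i1 = i, i2 = j, c1 = -1L, c2 = 1L,
                              multiple = n[j] - n[i])
    }
    out <- do.call(rbind, rows)
    out$i3 <- NA_integer_; out$c3 <- 0L
  } else {
    rows[[1]] <- data.frame(i1 = seq_len(N), i2 = NA_integer_,
                            c1 = 3L, c2 = 0L, multiple = 3L * n)
    if (N >= 2) {
      pr <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
      i <- pr[, 1]; j <- pr[, 2]
      # 2 n_i + n_j and |2 n_i - n_j| for ordered pairs, indices ascending
      rows[[2]] <- data.frame(i1 = i, i2 = j, c1 = 2L, c2 = 1L,
                              multiple = 2L * n[i] + n[j])
      rows[[3]] <- data.frame(i1 = i, i2 = j, c1 = 1L, c2 = 2L,
                              multiple = n[i] + 2L * n[j])
      m1 <- 2L * n[i] - n[j]
      rows[[4]] <- data.frame(i1 = i, i2 = j,
                              c1 = ifelse(m1 >= 0, 2L, -2L),
                              c2 = ifelse(m1 >= 0, -1L, 1L),
                              multiple = abs(m1))
      m2 <- 2L * n[j] - n[i]
      rows[[5]] <- data.frame(i1 = i, i2 = j,
                              c1 = ifelse(m2 >= 0, -1L, 1L),
                              c2 = ifelse(m2 >= 0, 2L, -2L),
                              multiple = abs(m2))
    }
    if (N >= 3) {
      tr <- t(utils::combn(N, 3))
      i <- tr[, 1]; j <- tr[, 2]; k <- tr[, 3]
      tri <- list(
        data.frame(i1 = i, i2 = j, i3 = k, c1 = 1L, c2 = 1L, c3 = 1L,
                   multiple = n[i] + n[j] + n[k]),
        {
          m <- n[i] + n[j] - n[k]
          data.frame(i1 = i, i2 = j, i3 = k,
                     c1 = ifelse(m >= 0, 1L, -1L), c2 = ifelse(m >= 0, 1L, -1L),
                     c3 = ifelse(m >= 0, -1L, 1L), multiple = abs(m))
        },
        {
          m <- n[i] - n[j] + n[k]
          data.frame(i1 = i, i2 = j, i3 = k,
                     c1 = ifelse(m >= 0, 1L, -1L), c2 = ifelse(m >= 0, -1L, 1L),
                     c3 = ifelse(m >= 0, 1L, -1L), multiple = abs(m))
        },
        {
          m <- -n[i] + n[j] + n[k]
          data.frame(i1 = i, i2 = j, i3 = k,
                     c1 = ifelse(m >= 0, -1L, 1L), c2 = ifelse(m >= 0, 1L, -1L),
                     c3 = ifelse(m >= 0, 1L, -1L), multiple = abs(m))
        }
      )
      pair_part <- do.call(rbind, rows[seq(2, min(5, length(rows)))])
      pair_part$i3 <- NA_integer_; pair_part$c3 <- 0L
      first <- rows[[1]]; first$i3 <- NA_integer_; first$c3 <- 0L
      out <- rbind(first, pair_part, do.call(rbind, tri))
      out <- out[out$multiple > 0L, , drop = FALSE]
      out$order <- 3L
      out$signature <- dp_signature(out)
      rownames(out) <- NULL
      return(out[, c("i1", "i2", "i3", "c1", "c2", "c3",
                     "multiple", "order", "signature")])
    }
    out <- do.call(rbind, lapply(rows, function(d) {
      if (!"i3" %in% names(d)) { d$i3 <- NA_integer_; d$c3 <- 0L }
      d
    }))
    out <- out[out$multiple > 0L, , drop = FALSE]
  }
  out$order <- as.integer(order)
  out$signature <- dp_signature(out)
  rownames(out) <- NULL
  out[, c("i1", "i2", "i3", "c1", "c2", "c3", "multiple", "order", "signature")]
}

# human-readable signature such as "2f1", "f1+f3", "2f2-f5"
dp_signature <- function(d) {
  term <- function(cc, ii) {
    out <- character(length(cc))
    use <- !is.na(ii) & cc != 0L
    mag <- abs(cc[use])
    out[use] <- paste0(ifelse(cc[use] < 0, "-", "+"),
                       ifelse(mag == 1L, "", mag), "f", ii[use])
    out
  }
  s <- paste0(term(d$c1, d$i1), term(d$c2, d$i2), term(d$c3, d$i3))
  sub("^\\+", "", s)
}

#' Check that a multiplier set yields unambiguous distortion products
#'
#' A PASS certificate guarantees: (i) all order-2 combination frequencies are
#' mutually distinct and distinct from every primary; (ii) all order-3
#' combination frequencies are distinct from every primary (when
#' `max_order_unambiguous >= 3`); and, in strict mode, (iii) the order-3 set
#' is also mutually distinct and disjoint from the order-2 set. Any violation
#' is reported with the signatures of both colliding combinations.
#'
#' @param multipliers distinct positive integers.
#' @param max_order_unambiguous 2 or 3 (default 3).
#' @param strict enforce condition (iii) (default `FALSE`; see
#'   [design_constraints()]).
#' @return a list of class `uniqueness_certificate` with elements `pass`
#'   (logical), `collisions` (data.frame of `multiple`, `signature_a`,
#'   `signature_b`), `n_dp2` (order-2 count), and `mode`.
#' @export
validate_uniqueness <- function(multipliers, max_order_unambiguous = 3,
                                strict = FALSE) {
  n <- sort(as.integer(multipliers))
  cert <- function(pass, collisions, n_dp2) {
    structure(list(pass = pass, collisions = collisions, n_dp2 = n_dp2,
                   mode = if (strict) "strict" else "relaxed"),
              class = "uniqueness_certificate")
  }
  empty <- data.frame(multiple = integer(), signature_a = character(),
                      signature_b = character())
  if (length(n) < 2) return(cert(TRUE, empty, length(n)^2))

  prim <- data.frame(multiple = n, signature = paste0("f", seq_along(n)))
  o2 <- enumerate_dp_frequencies(n, 2)
  pools <- list(
    rbind(prim[, c("multiple", "signature")],
          o2[, c("multiple", "signature")])
  )
  if (max_order_unambiguous >= 3) {
    o3 <- enumerate_dp_frequencies(n, 3)
    if (strict) {
      pools[[1]] <- rbind(pools[[1]], o3[, c("multiple", "signature")])
    } else {
      # order-3 checked against primaries only
      pools[[2]] <- rbind(prim[, c("multiple", "signature")],
                          o3[, c("multiple", "signature")])
      attr(pools[[2]], "restrict_to_primaries") <- TRUE
    }
  }
  coll <- list()
  for (p in pools) {
    dup_vals <- unique(p$multiple[duplicated(p$multiple)])
    for (v in dup_vals) {
      sigs <- p$signature[p$multiple == v]
      if (!is.null(attr(p, "restrict_to_primaries"))) {
        # report only collisions involving a primary
        if (!any(grepl("^f[0-9]+$", sigs))) next
      }
      coll[[length(coll) + 1L]] <- data.frame(
        multiple = v, signature_a = sigs[1], signature_b = sigs[2]
      )
    }
  }
  collisions <- if (length(coll)) do.call(rbind, coll) else empty
  cert(nrow(collisions) == 0L, collisions, nrow(o2))
}

#' @export
print.uniqueness_certificate <- function(x, ...) {
  cat(sprintf("zwuis uniqueness certificate (%s mode): %s\n", x$mode,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  order-2 combination frequencies: %d\n", x$n_dp2))
  if (!x$pass) {
    cat(sprintf("  %d collision(s), e.g. %s = %s at multiple %d\n",
                nrow(x$collisions), x$collisions$signature_a[1],
                x$collisions$signature_b[1], x$collisions$multiple[1]))
  }
  invisible(x)
}

# Incremental candidate check used by the design search. State holds logical
# occupancy tables indexed by frequency multiple, so membership is O(1).
new_search_state <- function(nmax, max_order) {
  L <- 3L * nmax + 1L
  list(S = integer(), prim = logical(L), o2 = logical(L),
       o3 = logical(L), max_order = max_order)
}

o3_values_for <- function(cand, S) {
  v <- 3L * cand
  if (length(S) >= 1) {
    v <- c(v, 2L * cand + S, abs(2L * cand - S), 2L * S + cand, abs(2L * S - cand))
  }
  if (length(S) >= 2) {
    pr <- which(upper.tri(matrix(0, length(S), length(S))), arr.ind = TRUE)
    ps <- S[pr[, 1]] + S[pr[, 2]]
    pd <- abs(S[pr[, 1]] - S[pr[, 2]])
    v <- c(v, cand + ps, abs(cand - ps), cand + pd, abs(cand - pd))
  }
  v[v > 0L]
}

try_add_multiplier <- function(state, cand, strict) {
  S <- state$S
  v2 <- if (length(S)) c(2L * cand, cand + S, abs(cand - S)) else 2L * cand
  if (state$o2[cand + 1L] || anyDuplicated(v2) ||
      any(state$o2[v2 + 1L]) || any(state$prim[v2 + 1L]) || any(v2 == cand)) {
    return(state) # rejected: order-2 ambiguity
  }
  v3 <- NULL
  if (state$max_order >= 3) {
    if (state$o3[cand + 1L]) return(state) # existing DP3 hits new primary
    v3 <- o3_values_for(cand, S)
    if (any(state$prim[v3 + 1L]) || any(v3 == cand)) return(state)
    if (strict) {
      if (anyDuplicated(v3) || any(state$o3[v3 + 1L]) ||
          any(state$o2[v3 + 1L]) || any(state$o3[v2 + 1L]) ||
          any(v3 %in% v2)) {
        return(state)
      }
    }
  }
  state$S <- c(S, cand)
  state$prim[cand + 1L] <- TRUE
  state$o2[v2 + 1L] <- TRUE
  if (!is.null(v3)) state$o3[v3 + 1L] <- TRUE
  state$accepted <- TRUE
  state
}

#' Design a zwuis stimulus by seeded randomized search
#'
#' Draws integer frequency multiples within the requested band (greedy
#' accept/reject with restarts) until `n_components` mutually compatible
#' multipliers are found, i.e. [validate_uniqueness()] passes in the requested
#' mode. Components are placed at the exact band edges first (when
#' compatible), so the design spans the stated band; remaining slots are
#' filled in seeded random order. Starting phases are drawn uniformly
#' (randomized across frequency) and levels start equal.
#'
#' @param constraints a [design_constraints()] object.
#' @return a [zwuis_stimulus()] whose uniqueness certificate passes.
#' @export
design_zwuis <- function(constraints) {
  stopifnot(inherits(constraints, "design_constraints"))
  cs <- constraints
  base <- cs$base_frequency_hz
  f_hi <- cs$f_max_hz
  if (!is.null(cs$cf_hz)) f_hi <- min(f_hi, cs$cf_fraction_limit * cs$cf_hz)
  f_hi <- min(f_hi, cs$sample_rate_hz / 2 - base)
  nmin <- as.integer(ceiling(cs$f_min_hz / base))
  nmax <- as.integer(floor(f_hi / base))
  pool_all <- seq.int(nmin, nmax)
  if (length(pool_all) < cs$n_components) {
    stop(sprintf(
      "infeasible design: only %d integer frequency slots in [%g, %g] Hz at base %g Hz (tightest constraint: band width vs base frequency)",
      length(pool_all), nmin * base, nmax * base, base
    ))
  }
  strict <- isTRUE(cs$strict)
  result <- withr::with_seed(cs$seed, {
    S_found <- NULL
    for (iter in seq_len(cs$max_search_iterations)) {
      pool <- sample(pool_all)
      if (isTRUE(cs$include_edges)) {
        pool <- c(nmin, nmax, pool[!pool %in% c(nmin, nmax)])
      }
      st <- new_search_state(nmax, cs$max_order_unambiguous)
      for (cand in pool) {
        st$accepted <- FALSE
        st <- try_add_multiplier(st, cand, strict)
        if (length(st$S) == cs$n_components) break
      }
      if (length(st$S) == cs$n_components) { S_found <- sort(st$S); break }
    }
    list(S = S_found, phases = stats::runif(cs$n_components))
  })
  if (is.null(result$S)) {
    stop(sprintf(
      "zwuis search failed after %d restarts (tightest constraint: %s-mode uniqueness at %d components in %d slots); widen the band, lower the base frequency, or relax the mode",
      cs$max_search_iterations, if (strict) "strict" else "relaxed",
      cs$n_components, length(pool_all)
    ))
  }
  stim <- zwuis_stimulus(
    multipliers = result$S,
    base_frequency_hz = base,
    levels_db_spl = cs$level_db_spl,
    phases_cycles = result$phases,
    duration_s = cs$duration_s,
    sample_rate_hz = cs$sample_rate_hz
  )
  attr(stim, "certificate") <- validate_uniqueness(
    result$S, cs$max_order_unambiguous, strict
  )
  stopifnot(attr(stim, "certificate")$pass)
  stim
}

#' Synthesize the pressure waveform of a zwuis stimulus
#'
#' Additive synthesis: the sum of cosines at the component frequencies with
#' amplitudes `reference_amplitude * 10^(level/20)` and phases
#' `2*pi*phase_cycles`. With the default reference of 20 uPa the output is in
#' pascal and levels are read as peak-amplitude dB SPL. The record is
#' coherent: a [coherent_dft()] at any component frequency returns the
#' specified amplitude and phase to numerical precision.
#'
#' @param stimulus a [zwuis_stimulus()].
#' @param reference_amplitude amplitude of a 0-dB component (default 20e-6,
#'   i.e. pascal output for dB SPL levels).
#' @return numeric waveform of length `duration_s * sample_rate_hz`.
#' @export
synthesize_waveform <- function(stimulus, reference_amplitude = 20e-6) {
  stopifnot(inherits(stimulus, "zwuis_stimulus"))
  fs <- stimulus$sample_rate_hz
  ns <- stimulus$duration_s * fs
  if (abs(ns - round(ns)) > 1e-6) {
    stop("duration_s * sample_rate_hz must be an integer number of samples")
  }
  n_base <- stimulus$duration_s * stimulus$base_frequency_hz
  if (abs(n_base - round(n_base)) > 1e-9) {
    stop("non-coherent duration: record must hold an integer number of base periods")
  }
  ns <- round(ns)
  t <- seq.int(0, ns - 1) / fs
  amps <- reference_amplitude * db_to_amp(stimulus$levels_db_spl)
  x <- numeric(ns)
  for (k in seq_along(stimulus$multipliers)) {
    x <- x + amps[k] * cos(2 * pi * (stimulus$component_frequencies_hz[k] * t +
                                       stimulus$phases_cycles[k]))
  }
  x
}

#' Write / read a zwuis stimulus specification as JSON
#'
#' @param stimulus a [zwuis_stimulus()].
#' @param path file path.
#' @return `write_stimulus_json` returns `path` invisibly;
#'   `read_stimulus_json` returns a [zwuis_stimulus()].
#' @export
write_stimulus_json <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "zwuis_stimulus"))
  jsonlite::write_json(unclass(stimulus), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_json
#' @export
read_stimulus_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  zwuis_stimulus(
    multipliers = x$multipliers,
    base_frequency_hz = x$base_frequency_hz,
    levels_db_spl = x$levels_db_spl,
    phases_cycles = x$phases_cycles,
    duration_s = x$duration_s,
    sample_rate_hz = x$sample_rate_hz
  )
}
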