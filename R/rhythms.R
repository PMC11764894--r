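#' Construct a single-channel EEG signal
#'
#' Container for one channel's sampled voltage trace. Samples are stored as a
#' plain numeric vector (conventionally microvolts) together with the
#' sampling rate and bookkeeping labels.
#'
#' @param samples Numeric vector of voltages; all values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel Channel label, e.g. `"O2"`.
#' @param trial_id Trial identifier.
#' @param t0 Segment start offset in seconds relative to trial onset.
#' @return Object of class `eeg_signal`.
#' @export
eeg_signal <- function(samples, fs, channel = "unknown", trial_id = NA, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive finite number")
  }
  if (length(samples) < 2L) stop("signal must contain at least 2 samples")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  structure(
    list(samples = samples, fs = fs, channel = as.character(channel),
         trial_id = trial_id, t0 = as.numeric(t0)),
    class = "eeg_signal"
  )
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> channel=%s trial=%s n=%d fs=%g Hz t0=%g s (%.3g s)\n",
              x$channel, as.character(x$trial_id), length(x$samples), x$fs,
              x$t0, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

.rhythm_names <- c("delta", "theta", "alpha", "beta", "gamma")

# Dyadic band edges of a >=4-level decomposition at sampling rate fs:
# delta 0 .. fs/32, theta fs/32 .. fs/16, alpha fs/16 .. fs/8,
# beta fs/8 .. fs/4, gamma fs/4 .. fs/2 (capped at Nyquist).
.dyadic_band_edges <- function(fs) {
  lo <- c(0, fs / 32, fs / 16, fs / 8, fs / 4)
  hi <- c(fs / 32, fs / 16, fs / 8, fs / 4, fs / 2)
  m <- cbind(low_hz = lo, high_hz = hi)
  rownames(m) <- .rhythm_names
  m
}

#' Decompose an EEG signal into the five brain rhythms
#'
#' Runs a multi-level discrete wavelet decomposition (default: db4, 4 levels)
#' and reconstructs each coefficient branch separately, zeroing all other
#' branches before the inverse transform. At `fs = 128` Hz and 4 levels the
#' branches map onto the canonical rhythms as A4 -> delta (0-4 Hz),
#' D4 -> theta (4-8), D3 -> alpha (8-16), D2 -> beta (16-32) and
#' D1 -> gamma (32-64). With more than 4 levels the extra low-frequency
#' detail branches are absorbed into delta so that the five reconstructions
#' always sum to the input exactly.
#'
#' @param signal An [eeg_signal()] (or bare numeric vector, in which case
#'   `fs` must be supplied via an `eeg_signal` — pass one).
#' @param wavelet_name Orthogonal wavelet, see [wavelet_filters()].
#' @param levels Decomposition depth, >= 4 (five rhythms need five branches).
#' @return Object of class `rhythm_set`: named list with `delta`, `theta`,
#'   `alpha`, `beta`, `gamma` numeric vectors (each the length of the input),
#'   `fs`, and `band_edges` (5 x 2 matrix of nominal dyadic edges in Hz).
#' @export
decompose_rhythms <- function(signal, wavelet_name = "db4", levels = 4) {
  if (!inherits(signal, "eeg_signal")) {
    stop("signal must be an eeg_signal object")
  }
  if (levels < 4) stop("levels must be >= 4 to resolve five rhythms")
  x <- signal$samples
  if (!all(is.finite(x))) stop("all samples must be finite")
  dec <- wavedec(x, wavelet_name = wavelet_name, levels = levels)

  gamma <- .wave_branch_rec(dec, 1L)
  beta  <- .wave_branch_rec(dec, 2L)
  alpha <- .wave_branch_rec(dec, 3L)
  theta <- .wave_branch_rec(dec, 4L)
  delta <- .wave_branch_rec(dec, "approx")
  if (levels > 4) {
    for (i in 5:levels) delta <- delta + .wave_branch_rec(dec, i)
  }

  edges <- .dyadic_band_edges(signal$fs)
  # nominal rhythm boundaries (theta/alpha/beta onsets and the beta/gamma
  # split); warn when the dyadic realization strays far from them
  nominal <- c(4, 8, 13, 30)
  realized <- edges[2:5, "low_hz"]
  dev <- abs(realized - nominal) / nominal
  if (any(dev > 0.25)) {
    warning(sprintf(
      "dyadic band boundaries (%s Hz) deviate more than 25%% from the nominal rhythm boundaries (%s Hz) at fs=%g",
      paste(signif(realized, 4), collapse = "/"),
      paste(nominal, collapse = "/"), signal$fs))
  }

  structure(
    list(delta = delta, theta = theta, alpha = alpha, beta = beta,
         gamma = gamma, fs = signal$fs, band_edges = edges,
         channel = signal$channel, trial_id = signal$trial_id),
    class = "rhythm_set"
  )
}

#' @export
print.rhythm_set <- function(x, ...) {
  cat(sprintf("<rhythm_set> channel=%s n=%d fs=%g Hz\n",
              x$channel, length(x$delta), x$fs))
  e <- x$band_edges
  for (b in rownames(e)) {
    cat(sprintf("  %-5s %5.3g-%.4g Hz  rms=%.4g\n", b, e[b, 1], e[b, 2],
                sqrt(mean(x[[b]]^2))))
  }
  invisible(x)
}

#' Sum the five rhythm reconstructions
#'
#' By linearity of the inverse filter bank this equals the original signal up
#' to floating-point error; exposed for reconstruction checks.
#'
#' @param rhythms A `rhythm_set`.
#' @return Numeric vector.
#' @export
rhythm_sum <- function(rhythms) {
  rhythms$delta + rhythms$theta + rhythms$alpha + rhythms$beta + rhythms$gamma
}
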