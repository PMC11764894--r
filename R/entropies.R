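#' Configuration for the six entropy estimators
#'
#' Bundles every tunable of the entropy feature set. Defaults follow the
#' dominant conventions of the nonlinear time-series literature: embedding
#' dimension `m = 2` with tolerance `r = 0.2 * SD(x)` for the
#' sample/fuzzy/approximate family, fuzzy weight exponent 2, ordinal patterns
#' of order 3 at delay 1, Welch spectra from 256-sample Hann segments with
#' 50% overlap, and a time-delay trajectory window of 10 samples for the
#' singular-spectrum estimator.
#'
#' @param m Embedding dimension (>= 1).
#' @param r_frac Tolerance as a fraction of the sequence standard deviation.
#' @param n_fuzzy Fuzzy membership weight exponent (> 0).
#' @param pe_order Ordinal pattern order (>= 2).
#' @param pe_delay Ordinal pattern delay in samples (>= 1).
#' @param eps Small positive constant guarding `log(0)`.
#' @param welch_nperseg Welch segment length in samples; `NULL` means
#'   `min(256, length(x))`.
#' @param welch_overlap_frac Welch segment overlap fraction in `[0, 1)`.
#' @param sse_window Trajectory-matrix window length L (>= 2, < series length).
#' @return Object of class `entropy_config`.
#' @export
entropy_config <- function(m = 2, r_frac = 0.2, n_fuzzy = 2,
                           pe_order = 3, pe_delay = 1, eps = 1e-12,
                           welch_nperseg = NULL, welch_overlap_frac = 0.5,
                           sse_window = 10) {
  stopifnot(m >= 1, r_frac > 0, n_fuzzy > 0, pe_order >= 2, pe_delay >= 1,
            eps > 0, sse_window >= 2,
            welch_overlap_frac >= 0, welch_overlap_frac < 1)
  structure(
    list(m = as.integer(m), r_frac = r_frac, n_fuzzy = n_fuzzy,
         pe_order = as.integer(pe_order), pe_delay = as.integer(pe_delay),
         eps = eps, welch_nperseg = welch_nperseg,
         welch_overlap_frac = welch_overlap_frac,
         sse_window = as.integer(sse_window)),
    class = "entropy_config"
  )
}

.as_series <- function(x) {
  if (inherits(x, "eeg_signal")) x <- x$samples
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("sequence contains non-finite values")
  x
}

#' Shannon entropy of a discrete weight vector
#'
#' Normalizes nonnegative weights to probabilities and returns
#' `-sum(p * log(p + eps))` (natural log). An all-zero weight vector gives 0.
#'
#' @param p Nonnegative weights (need not sum to 1).
#' @param eps Guard constant added inside the logarithm.
#' @param normalize Divide by `sum(p)` first (default `TRUE`).
#' @return Nonnegative scalar (up to `eps` slack), at most `log(length(p))`.
#' @export
shannon_entropy <- function(p, eps = 1e-12, normalize = TRUE) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("weights must be nonnegative")
  s <- sum(p)
  if (s <= 0) return(0)
  if (normalize) p <- p / s
  -sum(p * log(p + eps))
}

# Welch power spectral density, Hann window, one-sided spectrum.
# Scale factors are irrelevant downstream (the PSD is re-normalized).
.welch_psd <- function(x, fs, nperseg = NULL, overlap_frac = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(256L, n)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 2L) stop("sequence too short for a Welch spectrum")
  step <- max(1L, nperseg - as.integer(floor(nperseg * overlap_frac)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)
  nfreq <- nperseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    pw <- Mod(fft(seg))^2
    acc <- acc + pw[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  freq <- (seq_len(nfreq) - 1L) * fs / nperseg
  list(freq = freq, psd = psd)
}

#' Spectral entropy (PSDE)
#'
#' Shannon entropy of the Welch power spectral density normalized to unit
#' sum; quantifies how evenly signal energy spreads over frequency.
#'
#' @param x Numeric sequence or [eeg_signal()].
#' @param fs Sampling rate in Hz (ignored when `x` is an `eeg_signal`).
#' @param cfg An [entropy_config()].
#' @return Scalar in `[0, log(number of frequency bins)]`; an all-zero
#'   signal returns 0 by the degenerate-spectrum convention.
#' @export
spectral_entropy <- function(x, fs = NULL, cfg = entropy_config()) {
  if (inherits(x, "eeg_signal") && is.null(fs)) fs <- x$fs
  x <- .as_series(x)
  if (is.null(fs)) fs <- 1
  if (all(x == 0)) return(0)
  w <- .welch_psd(x, fs, cfg$welch_nperseg, cfg$welch_overlap_frac)
  shannon_entropy(w$psd, eps = cfg$eps)
}

#' Singular spectrum entropy (SSE)
#'
#' Shannon entropy of the normalized singular values of the L x (N - L + 1)
#' time-delay trajectory matrix; measures structural complexity (a pure
#' sinusoid has ~2 dominant singular values, broadband noise spreads them).
#'
#' @inheritParams spectral_entropy
#' @return Nonnegative scalar; a constant (rank-1) signal returns ~0.
#' @export
singular_spectrum_entropy <- function(x, cfg = entropy_config()) {
  x <- .as_series(x)
  n <- length(x)
  L <- cfg$sse_window
  if (n <= L) stop("sequence too short: need length > sse_window (", L, ")")
  K <- n - L + 1L
  traj <- matrix(0, L, K)
  for (i in seq_len(L)) traj[i, ] <- x[i:(i + K - 1L)]
  d <- svd(traj, nu = 0, nv = 0)$d
  if (sum(d) <= 0) return(0)
  shannon_entropy(d, eps = cfg$eps)
}

.check_embedding_length <- function(n, m) {
  if (n <= m + 1L) stop("sequence too short: need length > m + 1")
}

#' Sample entropy (SE)
#'
#' `-ln(phi(m+1, r) / phi(m, r))` with Chebyshev distance, self-matches
#' excluded, and `r = r_frac * SD(x)`. Both pattern counts use the same
#' template index set (the standard orientation: larger values = more
#' irregular).
#'
#' @inheritParams spectral_entropy
#' @return Nonnegative scalar. Constant input returns 0; when no length-m+1
#'   pair matches, returns the bounded cap `log(phi(m, r) * (N - m))`.
#' @export
sample_entropy <- function(x, cfg = entropy_config()) {
  x <- .as_series(x)
  .check_embedding_length(length(x), cfg$m)
  sdx <- sd(x)
  if (sdx == 0) return(0)
  r <- cfg$r_frac * sdx
  counts <- sampen_pair_counts(x, cfg$m, r)
  B <- counts[1]; A <- counts[2]
  if (B == 0) {
    warning("no template matches at length m; returning 0")
    return(0)
  }
  if (A == 0) return(log(B * (length(x) - cfg$m)))
  -log(A / B)
}

#' Fuzzy entropy (FE)
#'
#' Sample-entropy variant with mean-centered templates and graded matching
#' through the exponential membership `exp(-(d/r)^n)`; returned as
#' `ln(phi^m) - ln(phi^(m+1))`.
#'
#' @inheritParams spectral_entropy
#' @return Nonnegative scalar (up to numerical slack); constant input gives 0.
#' @export
fuzzy_entropy <- function(x, cfg = entropy_config()) {
  x <- .as_series(x)
  .check_embedding_length(length(x), cfg$m)
  sdx <- sd(x)
  if (sdx == 0) return(0)
  r <- cfg$r_frac * sdx
  phis <- fuzzyen_phi(x, cfg$m, r, cfg$n_fuzzy)
  log(phis[1]) - log(phis[2])
}

#' Approximate entropy (AE)
#'
#' `Phi^m(r) - Phi^(m+1)(r)` with `Phi` the template-mean of the natural log
#' of self-match-inclusive Chebyshev match fractions, `r = r_frac * SD(x)`.
#'
#' @inheritParams spectral_entropy
#' @return Scalar >= 0 up to numerical slack; constant input gives 0.
#' @export
approximate_entropy <- function(x, cfg = entropy_config()) {
  x <- .as_series(x)
  .check_embedding_length(length(x), cfg$m)
  sdx <- sd(x)
  if (sdx == 0) return(0)
  apen_cpp(x, cfg$m, cfg$r_frac * sdx)
}

# ordinal pattern codes for order d, delay tau; ties broken by earlier index
# (rank of position k = 1 + #{l: x_l < x_k, or x_l == x_k and l < k}),
# vectorized over all windows; returns one integer code per window
.ordinal_patterns <- function(x, d, tau) {
  n <- length(x)
  nt <- n - (d - 1L) * tau
  emb <- matrix(0, nt, d)
  for (k in seq_len(d)) emb[, k] <- x[seq(1L + (k - 1L) * tau, length.out = nt)]
  code <- numeric(nt)
  for (k in seq_len(d)) {
    rk <- numeric(nt)
    for (l in seq_len(d)) {
      if (l == k) next
      rk <- rk + (emb[, l] < emb[, k] | (emb[, l] == emb[, k] & l < k))
    }
    code <- code * d + rk
  }
  code
}

#' Permutation entropy (PE)
#'
#' Shannon entropy (natural log) of the distribution of ordinal rank
#' patterns of order `pe_order` at delay `pe_delay`; ranges from 0 (monotone
#' series, one pattern) to `ln(pe_order!)` (all patterns equally likely).
#' Ties are broken by earlier index.
#'
#' @inheritParams spectral_entropy
#' @return Scalar in `[0, log(factorial(pe_order))]`.
#' @export
permutation_entropy <- function(x, cfg = entropy_config()) {
  x <- .as_series(x)
  d <- cfg$pe_order; tau <- cfg$pe_delay
  if (length(x) < d * tau + 1L) {
    stop("sequence too short: need length >= pe_order * pe_delay + 1")
  }
  pat <- .ordinal_patterns(x, d, tau)
  p <- table(pat) / length(pat)
  -sum(p * log(p))
}

#' Compute all six entropies of one sequence
#'
#' Convenience wrapper returning the features in canonical BREM column order.
#'
#' @inheritParams spectral_entropy
#' @return Named numeric vector `c(AE, FE, SE, PE, SSE, PSDE)`.
#' @export
entropy_profile <- function(x, fs = NULL, cfg = entropy_config()) {
  if (inherits(x, "eeg_signal") && is.null(fs)) fs <- x$fs
  c(AE   = approximate_entropy(x, cfg),
    FE   = fuzzy_entropy(x, cfg),
    SE   = sample_entropy(x, cfg),
    PE   = permutation_entropy(x, cfg),
    SSE  = singular_spectrum_entropy(x, cfg),
    PSDE = spectral_entropy(x, fs = fs, cfg = cfg))
}
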