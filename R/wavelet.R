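# Orthogonal DWT filter bank with symmetric (half-point) boundary extension.
# Decomposition keeps floor((n + L - 1)/2) coefficients per branch, so the
# transform is slightly expansive but exactly invertible after trimming the
# synthesis output back to the analysis input length.

# Daubechies decomposition low-pass filters (sum = sqrt(2)).
.wavelet_dec_lo <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db1  = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(-0.12940952255092145, 0.22414386804185735,
           0.836516303737469, 0.48296291314469025),
  db4  = c(-0.010597401784997278, 0.032883011666982945,
           0.030841381835986965, -0.18703481171888114,
           -0.02798376941698385, 0.6308807679295904,
           0.7148465705525415, 0.23037781330885523)
)

#' Quadrature-mirror filter set of a named orthogonal wavelet
#'
#' @param name One of `"haar"`, `"db1"`, `"db2"`, `"db4"`.
#' @return List with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`
#'   (analysis/synthesis low/high-pass filters) and `length`.
#' @export
wavelet_filters <- function(name = "db4") {
  dec_lo <- .wavelet_dec_lo[[tolower(name)]]
  if (is.null(dec_lo)) {
    stop("unsupported wavelet '", name, "'; available: ",
         paste(names(.wavelet_dec_lo), collapse = ", "))
  }
  L <- length(dec_lo)
  rec_lo <- rev(dec_lo)
  rec_hi <- (-1)^(0:(L - 1)) * rev(rec_lo)
  list(dec_lo = dec_lo, dec_hi = rev(rec_hi),
       rec_lo = rec_lo, rec_hi = rec_hi, length = L)
}

.conv_full <- function(a, b) convolve(a, rev(b), type = "open")

# one analysis step: symmetric extension by L-1 samples each side,
# convolve, downsample by 2
.dwt_step <- function(x, f) {
  n <- length(x)
  L <- f$length
  stopifnot(n >= L)
  ext <- c(x[(L - 1):1], x, x[n:(n - L + 2)])
  nc <- (n + L - 1) %/% 2
  idx <- seq(L + 1, by = 2, length.out = nc)
  list(a = .conv_full(ext, f$dec_lo)[idx],
       d = .conv_full(ext, f$dec_hi)[idx])
}

# one synthesis step: upsample, convolve, trim to `out_len`
.idwt_step <- function(ca, cd, f, out_len) {
  nc <- length(ca)
  L <- f$length
  up <- function(cv) {
    u <- numeric(2 * nc)
    u[seq(1, by = 2, length.out = nc)] <- cv
    u
  }
  y <- .conv_full(up(ca), f$rec_lo) + .conv_full(up(cd), f$rec_hi)
  y <- y[(L - 1):(2 * nc)]
  y[seq_len(out_len)]
}

#' Multi-level discrete wavelet decomposition
#'
#' Cascades [wavelet_filters()] analysis steps on the approximation branch.
#'
#' @param x Numeric vector, length at least `2^levels * filter length`.
#' @param wavelet_name Wavelet name passed to [wavelet_filters()].
#' @param levels Number of decomposition levels (>= 1).
#' @return List with `approx` (level-`levels` approximation coefficients),
#'   `details` (list of detail coefficients, element i = level i),
#'   `lengths` (input length at each level, used for inversion),
#'   `wavelet`, `levels`.
#' @export
wavedec <- function(x, wavelet_name = "db4", levels = 4) {
  f <- wavelet_filters(wavelet_name)
  n <- length(x)
  if (levels < 1) stop("levels must be >= 1")
  if (n < 2^levels * f$length) {
    stop("insufficient length: need at least ", 2^levels * f$length,
         " samples for a ", levels, "-level '", wavelet_name,
         "' decomposition, got ", n)
  }
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- x
  for (i in seq_len(levels)) {
    lengths[i] <- length(a)
    st <- .dwt_step(a, f)
    details[[i]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, lengths = lengths,
       wavelet = wavelet_name, levels = levels)
}

# Reconstruct a single coefficient branch back to full signal length.
# `band` is "approx" or a detail level (integer in 1..levels).
.wave_branch_rec <- function(dec, band) {
  f <- wavelet_filters(dec$wavelet)
  L <- dec$levels
  if (identical(band, "approx")) {
    y <- dec$approx
    from <- L
  } else {
    y <- dec$details[[band]]
    from <- band
  }
  for (i in from:1) {
    zeros <- numeric(length(y))
    if (identical(band, "approx") && i == from) {
      y <- .idwt_step(y, zeros, f, dec$lengths[i])
    } else if (!identical(band, "approx") && i == from) {
      y <- .idwt_step(zeros, y, f, dec$lengths[i])
    } else {
      y <- .idwt_step(y, numeric(length(y)), f, dec$lengths[i])
    }
  }
  y
}
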