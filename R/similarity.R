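#' Configuration for BREM similarity measures
#'
#' @param flatten_order How a matrix is unrolled into a sequence for dynamic
#'   time warping: `"row"` (canonical; gamma row first, AE..PSDE within a
#'   row) or `"col"`.
#' @param mi_bins Histogram bin count for the mutual-information estimator.
#' @param jsc_bins Quantization level count for the Jaccard coefficient.
#' @return Object of class `similarity_config`.
#' @export
similarity_config <- function(flatten_order = c("row", "col"),
                              mi_bins = 5, jsc_bins = 5) {
  flatten_order <- match.arg(flatten_order)
  stopifnot(mi_bins >= 2, jsc_bins >= 2)
  structure(
    list(flatten_order = flatten_order, mi_bins = as.integer(mi_bins),
         jsc_bins = as.integer(jsc_bins)),
    class = "similarity_config"
  )
}

.similarity_score <- function(method, value, orientation) {
  structure(list(method = method, value = value, orientation = orientation),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> %s = %.6g (%s; %s)\n", x$method, x$value,
              x$orientation,
              if (x$orientation == "distance") "smaller = more similar"
              else "larger = more similar"))
  invisible(x)
}

.flatten <- function(x, cfg) {
  m <- .brem_values(x)
  if (cfg$flatten_order == "row") as.vector(t(m)) else as.vector(m)
}

.check_same_shape <- function(A, B) {
  a <- .brem_values(A); b <- .brem_values(B)
  if (!all(dim(a) == dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  invisible(NULL)
}

#' Dynamic time warping distance between two BREMs
#'
#' Flattens both matrices in the configured canonical order and runs the
#' classical dynamic-programming recurrence
#' `C(i,j) = |A_i - B_j| + min(C(i-1,j), C(i,j-1), C(i-1,j-1))`,
#' returning the terminal cumulative cost. Symmetric, zero iff the flattened
#' sequences are identical.
#'
#' @param A,B BREMs, region BREMs, matrices of equal shape, or numeric
#'   vectors (vectors may differ in length; warping absorbs the difference).
#' @param cfg A [similarity_config()].
#' @return A `similarity_score` with orientation `"distance"`.
#' @export
dtw_distance <- function(A, B, cfg = similarity_config()) {
  if (!(is.numeric(A) && is.null(dim(A)))) .check_same_shape(A, B)
  a <- .flatten(A, cfg); b <- .flatten(B, cfg)
  .similarity_score("DTW", dtw_cpp(a, b), "distance")
}

.equal_width_bins <- function(a, b, bins) {
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(NULL)
  la <- pmin(floor((a - rng[1]) / diff(rng) * bins) + 1L, bins)
  lb <- pmin(floor((b - rng[1]) / diff(rng) * bins) + 1L, bins)
  list(a = la, b = lb)
}

#' Mutual information between two BREMs
#'
#' Discretizes both matrices into `mi_bins` equal-width bins over their
#' pooled range and computes `MI = H(A) + H(B) - H(A, B)` from the joint
#' histogram of co-located entries (natural log).
#'
#' @inheritParams dtw_distance
#' @return A `similarity_score` with orientation `"similarity"`; value >= 0.
#' @export
mutual_information <- function(A, B, cfg = similarity_config()) {
  .check_same_shape(A, B)
  a <- .flatten(A, cfg); b <- .flatten(B, cfg)
  if (length(a) < 2L) stop("need at least 2 entries")
  lv <- .equal_width_bins(a, b, cfg$mi_bins)
  if (is.null(lv)) {
    warning("constant matrices: mutual information is 0 by convention")
    return(.similarity_score("MI", 0, "similarity"))
  }
  joint <- table(factor(lv$a, levels = seq_len(cfg$mi_bins)),
                 factor(lv$b, levels = seq_len(cfg$mi_bins))) / length(a)
  hh <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- hh(rowSums(joint)) + hh(colSums(joint)) - hh(joint)
  .similarity_score("MI", max(mi, 0), "similarity")
}

#' Spearman rank correlation between two BREMs
#'
#' Flattens both matrices, ranks with average ranks for ties, and returns the
#' Pearson correlation of the ranks (equal to the classical
#' `1 - 6*sum(d^2)/(n*(n^2-1))` formula when tie-free).
#'
#' @inheritParams dtw_distance
#' @return A `similarity_score` with orientation `"similarity"`,
#'   value in `[-1, 1]`; zero (with a warning) when either rank vector is
#'   constant.
#' @export
spearman_similarity <- function(A, B, cfg = similarity_config()) {
  .check_same_shape(A, B)
  a <- .flatten(A, cfg); b <- .flatten(B, cfg)
  if (length(a) < 3L) stop("need at least 3 entries")
  ra <- rank(a); rb <- rank(b)
  va <- sum((ra - mean(ra))^2); vb <- sum((rb - mean(rb))^2)
  if (va == 0 || vb == 0) {
    warning("zero rank variance: Spearman correlation is 0 by convention")
    return(.similarity_score("SCC", 0, "similarity"))
  }
  rho <- sum((ra - mean(ra)) * (rb - mean(rb))) / sqrt(va * vb)
  .similarity_score("SCC", rho, "similarity")
}

#' Jaccard dissimilarity between two BREMs
#'
#' Quantizes each entry to `jsc_bins` equal-width levels over the pooled
#' range, forms the sets of (cell position, level) pairs and returns
#' `1 - |intersection| / |union|`: 0 for identical quantized matrices, 1 for
#' wholly disjoint ones. Treated as a distance by the classifier.
#'
#' @inheritParams dtw_distance
#' @return A `similarity_score` with orientation `"distance"`,
#'   value in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(A, B, cfg = similarity_config()) {
  .check_same_shape(A, B)
  a <- .flatten(A, cfg); b <- .flatten(B, cfg)
  lv <- .equal_width_bins(a, b, cfg$jsc_bins)
  if (is.null(lv)) {
    # identical constant matrices quantize to the same set
    return(.similarity_score("JSC", 0, "distance"))
  }
  inter <- sum(lv$a == lv$b)
  union <- 2L * length(a) - inter
  .similarity_score("JSC", 1 - inter / union, "distance")
}

.similarity_methods <- list(
  dtw = dtw_distance,
  mi  = mutual_information,
  scc = spearman_similarity,
  jsc = jaccard_dissimilarity
)

#' Compute a named similarity measure
#'
#' @inheritParams dtw_distance
#' @param method One of `"dtw"`, `"mi"`, `"scc"`, `"jsc"`
#'   (case-insensitive).
#' @return A `similarity_score`.
#' @export
brem_similarity <- function(A, B, method = "dtw", cfg = similarity_config()) {
  method <- tolower(method)
  fn <- .similarity_methods[[method]]
  if (is.null(fn)) stop("unknown similarity method '", method, "'")
  fn(A, B, cfg)
}
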