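# Canonical BREM layout: rows are rhythms from fastest to slowest, columns
# the six entropies. Both orders are fixed and part of the data contract.
BREM_ROW_ORDER <- c("gamma", "beta", "alpha", "theta", "delta")
BREM_COL_ORDER <- c("AE", "FE", "SE", "PE", "SSE", "PSDE")

#' Default brain-region channel map (32-channel montage)
#'
#' Five anatomical regions covering the standard 32-channel emotion-EEG
#' montage: Frontal and Central and Parietal (7 channels each), Temporal (6)
#' and Occipital (5). The listing order within a region is the fusion order
#' used by [fuse_region()].
#'
#' @return Named list of character vectors, region -> ordered channel labels.
#' @export
region_map_default <- function() {
  list(
    Frontal   = c("FP1", "FP2", "AF3", "AF4", "F3", "FZ", "F4"),
    Central   = c("FC5", "FC1", "FC2", "FC6", "C3", "CZ", "C4"),
    Parietal  = c("CP5", "CP1", "CP2", "CP6", "P3", "PZ", "P4"),
    Temporal  = c("F7", "F8", "T7", "T8", "P7", "P8"),
    Occipital = c("PO3", "PO4", "O1", "OZ", "O2")
  )
}

#' Full montage channel order
#'
#' All 32 channel labels, concatenated region by region; this is the
#' deterministic tie-break order for channel grid search.
#'
#' @param map A region map as returned by [region_map_default()].
#' @return Character vector of channel labels.
#' @export
montage_channels <- function(map = region_map_default()) {
  unname(unlist(map, use.names = FALSE))
}

#' Build the Brain Rhythm Entropy Matrix of one channel
#'
#' Decomposes the signal into the five rhythms, computes the six entropies on
#' every rhythm and fills the fixed 5 x 6 matrix: rows gamma, beta, alpha,
#' theta, delta; columns AE, FE, SE, PE, SSE, PSDE.
#'
#' @param signal An [eeg_signal()].
#' @param cfg An [entropy_config()].
#' @param wavelet_name,levels Passed to [decompose_rhythms()].
#' @param standardize If `TRUE`, z-score the 30 entries after computation
#'   (off by default; the canonical matrix is unnormalized).
#' @return Object of class `brem` with fields `values` (5 x 6 named matrix),
#'   `channel`, `window` (c(t0, t1) in seconds), `fs`.
#' @export
build_brem <- function(signal, cfg = entropy_config(), wavelet_name = "db4",
                       levels = 4, standardize = FALSE) {
  rs <- decompose_rhythms(signal, wavelet_name = wavelet_name, levels = levels)
  vals <- matrix(NA_real_, 5, 6,
                 dimnames = list(BREM_ROW_ORDER, BREM_COL_ORDER))
  for (rw in BREM_ROW_ORDER) {
    prof <- tryCatch(
      entropy_profile(rs[[rw]], fs = signal$fs, cfg = cfg),
      error = function(e) {
        stop("BREM cell (", rw, ", *): ", conditionMessage(e), call. = FALSE)
      })
    vals[rw, ] <- prof[BREM_COL_ORDER]
  }
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop("BREM cell (", BREM_ROW_ORDER[bad[1]], ", ", BREM_COL_ORDER[bad[2]],
         "): non-finite entropy value")
  }
  if (standardize) {
    s <- sd(vals)
    vals <- if (s > 0) (vals - mean(vals)) / s else vals * 0
  }
  t0 <- signal$t0
  structure(
    list(values = vals, channel = signal$channel,
         window = c(t0, t0 + length(signal$samples) / signal$fs),
         fs = signal$fs, trial_id = signal$trial_id),
    class = "brem"
  )
}

#' @export
print.brem <- function(x, digits = 4, ...) {
  cat(sprintf("<brem> channel=%s window=[%g, %g] s\n",
              x$channel, x$window[1], x$window[2]))
  print(round(x$values, digits))
  invisible(x)
}

#' Fuse single-channel BREMs into a region BREM
#'
#' Horizontally concatenates the 5 x 6 matrices of channels belonging to one
#' anatomical region, in the region map's listing order. Rows remain the five
#' rhythms; an occipital fusion of 5 channels yields a 5 x 30 matrix. Pure
#' concatenation: every input entry is preserved.
#'
#' @param brems List of [build_brem()] results, all from the same window.
#' @param region Region name present in `map`.
#' @param map Region map, see [region_map_default()].
#' @return Object of class `region_brem` with fields `values`
#'   (5 x (6 * C) matrix), `region`, `channel_order`, `window`.
#' @export
fuse_region <- function(brems, region, map = region_map_default()) {
  if (!region %in% names(map)) {
    stop("unknown region '", region, "'; expected one of ",
         paste(names(map), collapse = ", "))
  }
  if (length(brems) < 1L) stop("need at least one BREM to fuse")
  chans <- vapply(brems, function(b) b$channel, character(1))
  bad <- setdiff(chans, map[[region]])
  if (length(bad) > 0) {
    stop("channel(s) not in region '", region, "': ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(chans)) {
    stop("duplicate channel(s): ",
         paste(unique(chans[duplicated(chans)]), collapse = ", "))
  }
  wins <- t(vapply(brems, function(b) b$window, numeric(2)))
  if (max(wins[, 1]) - min(wins[, 1]) > 1e-9 ||
      max(wins[, 2]) - min(wins[, 2]) > 1e-9) {
    stop("all BREMs must come from the same time window")
  }
  ord <- order(match(chans, map[[region]]))
  brems <- brems[ord]
  chans <- chans[ord]
  blocks <- lapply(brems, function(b) {
    m <- b$values
    colnames(m) <- paste(b$channel, colnames(m), sep = ".")
    m
  })
  structure(
    list(values = do.call(cbind, blocks), region = region,
         channel_order = chans, window = brems[[1]]$window),
    class = "region_brem"
  )
}

#' @export
print.region_brem <- function(x, ...) {
  cat(sprintf("<region_brem> region=%s channels=%s dim=%dx%d\n",
              x$region, paste(x$channel_order, collapse = ","),
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# extract the numeric matrix from brem / region_brem / plain matrix input
.brem_values <- function(x) {
  if (inherits(x, "brem") || inherits(x, "region_brem")) return(x$values)
  if (is.matrix(x)) return(x)
  if (is.numeric(x)) return(matrix(x, nrow = 1))
  stop("expected a brem, region_brem, matrix or numeric vector")
}
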