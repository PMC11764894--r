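#' Construct a labeled set of EEG trials for one subject
#'
#' @param subject Subject identifier.
#' @param trials List of trials; each trial is a list with `trial_id`,
#'   either `label` (`"positive"`/`"negative"`) or a numeric `rating`
#'   (mapped by the >= 5 rule: rating >= 5 is positive), and `data`, a named
#'   list mapping channel label -> numeric sample vector.
#' @param fs Common sampling rate in Hz.
#' @param dimension `"arousal"` or `"valence"` (bookkeeping only).
#' @return Object of class `trial_set`.
#' @export
trial_set <- function(subject, trials, fs, dimension = "arousal") {
  if (length(trials) < 1L) stop("need at least one trial")
  trials <- lapply(trials, function(tr) {
    if (is.null(tr$label)) {
      if (is.null(tr$rating)) stop("trial needs a label or a rating")
      tr$label <- if (tr$rating >= 5) "positive" else "negative"
    }
    if (!tr$label %in% c("positive", "negative")) {
      stop("label must be 'positive' or 'negative'")
    }
    if (is.null(tr$data) || length(tr$data) < 1L || is.null(names(tr$data))) {
      stop("trial needs a named list of per-channel sample vectors")
    }
    tr
  })
  ns <- unique(vapply(trials, function(tr) length(tr$data[[1]]), integer(1)))
  if (length(ns) != 1L) stop("all trials must have the same length")
  structure(
    list(subject = subject, trials = trials, fs = fs, dimension = dimension),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  labs <- trial_labels(x)
  cat(sprintf(
    "<trial_set> subject=%s dimension=%s trials=%d (%d positive / %d negative) channels=%s fs=%g Hz\n",
    x$subject, x$dimension, length(x$trials),
    sum(labs == "positive"), sum(labs == "negative"),
    paste(names(x$trials[[1]]$data), collapse = ","), x$fs))
  invisible(x)
}

#' Labels of every trial in a trial set
#' @param trials A [trial_set()].
#' @return Character vector of `"positive"`/`"negative"`.
#' @export
trial_labels <- function(trials) {
  vapply(trials$trials, function(tr) tr$label, character(1))
}

#' Extract one channel of one trial as an [eeg_signal()]
#' @param trials A [trial_set()].
#' @param index Trial index.
#' @param channel Channel label.
#' @return An `eeg_signal`.
#' @export
trial_signal <- function(trials, index, channel) {
  tr <- trials$trials[[index]]
  if (!channel %in% names(tr$data)) {
    stop("channel '", channel, "' not present in trial ", tr$trial_id)
  }
  eeg_signal(tr$data[[channel]], fs = trials$fs, channel = channel,
             trial_id = tr$trial_id)
}

#' Cut a contiguous segment out of a trial signal
#'
#' Segments live on a non-overlapping grid anchored at 0 s: `start_s` must be
#' a multiple of `window_s` and the window must fit inside the trial.
#'
#' @param signal An [eeg_signal()].
#' @param window_s Window length in seconds (e.g. 5, 10, 20, 30).
#' @param start_s Segment start in seconds.
#' @return An `eeg_signal` of `window_s * fs` samples with `t0 = start_s`.
#' @export
segment_trial <- function(signal, window_s, start_s = 0) {
  stopifnot(inherits(signal, "eeg_signal"), window_s > 0, start_s >= 0)
  dur <- length(signal$samples) / signal$fs
  if (abs(start_s / window_s - round(start_s / window_s)) > 1e-9) {
    stop("start_s (", start_s, ") must be a multiple of window_s (",
         window_s, ")")
  }
  if (start_s + window_s > dur + 1e-9) {
    stop("segment [", start_s, ", ", start_s + window_s,
         "] s exceeds trial duration ", dur, " s")
  }
  nw <- round(window_s * signal$fs)
  if (abs(nw - window_s * signal$fs) > 1e-9) {
    stop("window_s * fs must be an integer sample count")
  }
  i0 <- round(start_s * signal$fs)
  eeg_signal(signal$samples[(i0 + 1):(i0 + nw)], fs = signal$fs,
             channel = signal$channel, trial_id = signal$trial_id,
             t0 = start_s)
}

#' Number of non-overlapping segments available in a trial
#' @param duration_s Trial duration in seconds.
#' @param window_s Window length in seconds.
#' @return Integer segment count; starts are `0, window_s, 2*window_s, ...`.
#' @export
n_segments <- function(duration_s, window_s) {
  as.integer(floor(duration_s / window_s + 1e-9))
}

#' Classification accuracy from confusion counts
#'
#' @param TP,FP,FN,TN Nonnegative confusion counts, positive total.
#' @return `(TP + TN) / (TP + FP + FN + TN)`.
#' @export
accuracy <- function(TP, FP, FN, TN) {
  if (any(c(TP, FP, FN, TN) < 0)) stop("counts must be nonnegative")
  tot <- TP + FP + FN + TN
  if (any(tot <= 0)) stop("total count must be positive")
  (TP + TN) / tot
}

#' Classify a test BREM against one positive and one negative template
#'
#' Computes the similarity of the test matrix to both templates and assigns
#' the class of the more similar one, honoring the measure's orientation
#' (DTW/JSC: smaller wins; MI/SCC: larger wins). An exact tie predicts
#' positive and is flagged via the `"tie"` attribute.
#'
#' @param test,pos_template,neg_template BREMs of identical shape.
#' @param method Similarity method, see [brem_similarity()].
#' @param cfg A [similarity_config()].
#' @return `"positive"` or `"negative"`, with logical attribute `"tie"`.
#' @export
classify_by_template <- function(test, pos_template, neg_template,
                                 method = "dtw", cfg = similarity_config()) {
  sp <- brem_similarity(test, pos_template, method, cfg)
  sn <- brem_similarity(test, neg_template, method, cfg)
  tie <- sp$value == sn$value
  pos_wins <- if (sp$orientation == "distance") sp$value <= sn$value
              else sp$value >= sn$value
  structure(if (pos_wins) "positive" else "negative", tie = tie)
}

# Build one BREM per trial for a channel- or region-mode evaluation.
.trial_brems <- function(trials, window_s, segment_start_s, channel = NULL,
                         region = NULL, cfg = entropy_config(),
                         map = region_map_default(), wavelet_name = "db4",
                         levels = 4) {
  if (is.null(channel) == is.null(region)) {
    stop("specify exactly one of 'channel' or 'region'")
  }
  lapply(seq_along(trials$trials), function(k) {
    if (!is.null(channel)) {
      sig <- segment_trial(trial_signal(trials, k, channel), window_s,
                           segment_start_s)
      build_brem(sig, cfg, wavelet_name = wavelet_name, levels = levels)
    } else {
      have <- intersect(map[[region]], names(trials$trials[[k]]$data))
      if (length(have) < 1L) {
        stop("no channels of region '", region, "' present in trial data")
      }
      bs <- lapply(have, function(ch) {
        sig <- segment_trial(trial_signal(trials, k, ch), window_s,
                             segment_start_s)
        build_brem(sig, cfg, wavelet_name = wavelet_name, levels = levels)
      })
      fuse_region(bs, region, map)
    }
  })
}

#' Leave-one-out template-cycling evaluation
#'
#' The exhaustive template protocol: every ordered pair of one negative and
#' one positive trial serves once as the (negative, positive) template pair;
#' all remaining trials are classified against the two templates by
#' [classify_by_template()], filling one confusion record per pair. With 16
#' negative and 24 positive trials this yields 16 x 24 = 384 evaluations of
#' 38 test trials each. Per-pair accuracies are averaged into the subject
#' score.
#'
#' @param trials A [trial_set()] with at least one trial of each class (and
#'   at least 3 trials overall so every pair has a non-empty test set).
#' @param method Similarity method (`"dtw"`, `"mi"`, `"scc"`, `"jsc"`).
#' @param window_s Segment window length in seconds.
#' @param channel Channel label (single-channel mode), or `NULL`.
#' @param region Region name (single-region mode), or `NULL`.
#' @param segment_start_s Segment start in seconds (multiple of `window_s`).
#' @param cfg An [entropy_config()].
#' @param sim_cfg A [similarity_config()].
#' @param map Region map for region mode.
#' @param wavelet_name,levels Passed to [decompose_rhythms()].
#' @return Object of class `evaluation_report`: list with `pairs` (one row
#'   per template pair: `pos_template_id`, `neg_template_id`, `TP`, `FP`,
#'   `FN`, `TN`, `accuracy`), `mean_accuracy`, `sd_accuracy`, `n_pairs`,
#'   `tie_count` and a `config` echo.
#' @export
loocv_template_evaluation <- function(trials, method = "dtw", window_s = 5,
                                      channel = NULL, region = NULL,
                                      segment_start_s = 0,
                                      cfg = entropy_config(),
                                      sim_cfg = similarity_config(),
                                      map = region_map_default(),
                                      wavelet_name = "db4", levels = 4) {
  labs <- trial_labels(trials)
  pos_idx <- which(labs == "positive")
  neg_idx <- which(labs == "negative")
  if (length(pos_idx) < 1L || length(neg_idx) < 1L) {
    stop("need at least one positive and one negative trial")
  }
  if (length(labs) < 3L) {
    stop("empty test set: need at least 3 trials")
  }
  brems <- .trial_brems(trials, window_s, segment_start_s, channel = channel,
                        region = region, cfg = cfg, map = map,
                        wavelet_name = wavelet_name, levels = levels)
  ids <- vapply(trials$trials, function(tr) as.character(tr$trial_id),
                character(1))

  # all four measures are symmetric: precompute the pairwise score matrix
  n <- length(brems)
  S <- matrix(0, n, n)
  orientation <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sc <- brem_similarity(brems[[i]], brems[[j]], method, sim_cfg)
      S[i, j] <- S[j, i] <- sc$value
      orientation <- sc$orientation
    }
  }
  dist_like <- identical(orientation, "distance")

  rows <- vector("list", length(neg_idx) * length(pos_idx))
  tie_count <- 0L
  k <- 0L
  for (ni in neg_idx) {
    for (pj in pos_idx) {
      test_idx <- setdiff(seq_len(n), c(ni, pj))
      sp <- S[test_idx, pj]
      sn <- S[test_idx, ni]
      pred_pos <- if (dist_like) sp <= sn else sp >= sn
      tie_count <- tie_count + sum(sp == sn)
      truth_pos <- labs[test_idx] == "positive"
      TP <- sum(pred_pos & truth_pos)
      FP <- sum(pred_pos & !truth_pos)
      FN <- sum(!pred_pos & truth_pos)
      TN <- sum(!pred_pos & !truth_pos)
      k <- k + 1L
      rows[[k]] <- data.frame(
        pos_template_id = ids[pj], neg_template_id = ids[ni],
        TP = TP, FP = FP, FN = FN, TN = TN,
        accuracy = accuracy(TP, FP, FN, TN),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  structure(
    list(pairs = pairs,
         mean_accuracy = mean(pairs$accuracy),
         sd_accuracy = if (nrow(pairs) > 1) sd(pairs$accuracy) else 0,
         n_pairs = nrow(pairs), tie_count = tie_count,
         config = list(subject = trials$subject,
                       dimension = trials$dimension, method = method,
                       window_s = window_s,
                       channel = if (is.null(channel)) NA else channel,
                       region = if (is.null(region)) NA else region,
                       segment_start_s = segment_start_s)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<evaluation_report> subject=%s %s method=%s window=%gs %s=%s segment=%g-%g s\n",
    cfg$subject, cfg$dimension, cfg$method, cfg$window_s,
    if (is.na(cfg$channel)) "region" else "channel",
    if (is.na(cfg$channel)) cfg$region else cfg$channel,
    cfg$segment_start_s, cfg$segment_start_s + cfg$window_s))
  cat(sprintf("  %d template pairs, mean accuracy %.2f%% (sd %.2f%%), %d tie(s)\n",
              x$n_pairs, 100 * x$mean_accuracy, 100 * x$sd_accuracy,
              x$tie_count))
  invisible(x)
}

#' Grid search over channels and time segments
#'
#' Runs [loocv_template_evaluation()] for every (channel, segment) cell and
#' returns the cell with the highest mean accuracy. Ties are broken
#' deterministically: first channel in montage order, then earliest segment.
#'
#' @param trials A [trial_set()].
#' @param method Similarity method.
#' @param window_s Segment window length in seconds.
#' @param candidate_channels Channels to search; default: all channels in the
#'   trial data, in montage order.
#' @param segment_starts Segment starts in seconds; default: the full
#'   non-overlapping grid that fits the trial duration.
#' @param ... Passed to [loocv_template_evaluation()].
#' @return List with `channel`, `segment_start`, `mean_accuracy` and `grid`
#'   (a data.frame of every cell's mean/sd accuracy).
#' @export
grid_search_best <- function(trials, method = "dtw", window_s = 5,
                             candidate_channels = NULL,
                             segment_starts = NULL, ...) {
  if (is.null(candidate_channels)) {
    candidate_channels <- names(trials$trials[[1]]$data)
  }
  if (length(candidate_channels) < 1L) stop("need at least one channel")
  mont <- montage_channels()
  pos <- match(candidate_channels, mont)
  pos[is.na(pos)] <- length(mont) + seq_len(sum(is.na(pos)))
  candidate_channels <- candidate_channels[order(pos)]
  if (is.null(segment_starts)) {
    dur <- length(trials$trials[[1]]$data[[1]]) / trials$fs
    ns <- n_segments(dur, window_s)
    if (ns < 1L) stop("no segment of ", window_s, " s fits the trials")
    segment_starts <- (seq_len(ns) - 1) * window_s
  }
  grid <- list()
  best <- NULL
  for (ch in candidate_channels) {
    for (s0 in segment_starts) {
      rep_ <- loocv_template_evaluation(trials, method = method,
                                        window_s = window_s, channel = ch,
                                        segment_start_s = s0, ...)
      grid[[length(grid) + 1L]] <- data.frame(
        channel = ch, segment_start = s0,
        mean_accuracy = rep_$mean_accuracy,
        sd_accuracy = rep_$sd_accuracy, stringsAsFactors = FALSE)
      if (is.null(best) || rep_$mean_accuracy > best$mean_accuracy) {
        best <- list(channel = ch, segment_start = s0,
                     mean_accuracy = rep_$mean_accuracy)
      }
    }
  }
  c(best, list(grid = do.call(rbind, grid)))
}

#' Two-group one-way ANOVA screen for a single feature
#'
#' Closed-form one-way ANOVA with two groups (F equals the squared pooled
#' two-sample t statistic). Used to report the significance of selected BREM
#' cells; p-values are unadjusted.
#'
#' @param feature_values Numeric vector of one feature across observations.
#' @param labels Two-level grouping (factor, character or logical), at least
#'   two observations per group.
#' @return List with `F`, `p`, `df` (c(1, n - 2)).
#' @export
anova_feature_screen <- function(feature_values, labels) {
  y <- as.numeric(feature_values)
  g <- as.factor(labels)
  if (nlevels(g) != 2L) stop("labels must have exactly two levels")
  if (any(table(g) < 2L)) stop("need at least 2 observations per group")
  n <- length(y)
  gm <- tapply(y, g, mean)
  ng <- tapply(y, g, length)
  ssb <- sum(ng * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df <- c(1, n - 2L)
  if (ssw == 0) {
    if (ssb == 0) {
      warning("zero variance within and between groups: degenerate F = 0, p = 1")
      return(list(F = 0, p = 1, df = df))
    }
    warning("zero within-group variance: degenerate F = Inf, p = 0")
    return(list(F = Inf, p = 0, df = df))
  }
  Fstat <- (ssb / df[1]) / (ssw / df[2])
  list(F = Fstat, p = pf(Fstat, df[1], df[2], lower.tail = FALSE), df = df)
}
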