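# small synthetic subjects keep the protocol tests fast
make_subject <- function(n_pos, n_neg, seed = 1, trial_s = 5, effect = 1,
                         n_channels = 1, ...) {
  cfg <- synthetic_config(effect = effect, trial_s = trial_s, n_pos = n_pos,
                          n_neg = n_neg, n_channels = n_channels,
                          seed = seed, ...)
  list(cfg = cfg, trials = generate_subject(cfg))
}

test_that("segment_trial cuts on the non-overlapping grid", {
  sig <- eeg_signal(rnorm(60 * 128), 128, channel = "O2", trial_id = "t1")
  seg <- segment_trial(sig, 5, 0)
  expect_identical(length(seg), 640L)
  expect_identical(seg$t0, 0)
  seg3 <- segment_trial(sig, 5, 15)
  expect_identical(seg3$samples, sig$samples[(15 * 128 + 1):(20 * 128)])
  expect_identical(seg3$t0, 15)
  expect_identical(n_segments(60, 5), 12L)
  expect_error(segment_trial(sig, 5, 58), "multiple")
  expect_error(segment_trial(sig, 5, 60), "exceeds")
  expect_error(segment_trial(sig, 30, 60), "exceeds")
})

test_that("accuracy implements the confusion-count ratio", {
  expect_equal(accuracy(23, 15, 0, 0), 23 / 38)
  expect_equal(round(accuracy(23, 15, 0, 0), 4), 0.6053)
  expect_identical(accuracy(0, 0, 0, 10), 1)
  expect_identical(accuracy(1, 1, 1, 1), 0.5)
  expect_error(accuracy(0, 0, 0, 0), "positive")
  expect_error(accuracy(-1, 0, 0, 2), "nonnegative")
})

test_that("template classification honors orientation and breaks ties positive", {
  pos <- small_brem(91, "C3")
  neg <- small_brem(92, "C3")
  expect_identical(as.character(classify_by_template(pos, pos, neg, "dtw")),
                   "positive")
  expect_identical(as.character(classify_by_template(neg, pos, neg, "dtw")),
                   "negative")
  # MI: self-similarity equals H(test), above MI with an unrelated matrix
  set.seed(4)
  neg_m <- matrix(rnorm(30), 5)
  pos_m <- matrix(rnorm(30), 5)
  expect_gt(mutual_information(neg_m, neg_m)$value,
            mutual_information(neg_m, pos_m)$value)
  expect_identical(as.character(classify_by_template(neg_m, pos_m, neg_m, "mi")),
                   "negative")
  # forced tie: identical templates
  out <- classify_by_template(neg, pos, pos, "dtw")
  expect_identical(as.character(out), "positive")
  expect_true(attr(out, "tie"))
})

test_that("LOOCV enumerates n_neg x n_pos pairs of 38-of-40 test splits", {
  sub <- make_subject(n_pos = 4, n_neg = 3, seed = 5)
  rep_ <- loocv_template_evaluation(sub$trials, "dtw", 5,
                                    channel = sub$cfg$signal_channel)
  expect_identical(rep_$n_pairs, 12L)
  expect_identical(nrow(rep_$pairs), 12L)
  # every pair tests all trials except its two templates
  expect_true(all(rowSums(rep_$pairs[, c("TP", "FP", "FN", "TN")]) == 5))
  expect_true(all(rep_$pairs$accuracy ==
                  accuracy(rep_$pairs$TP, rep_$pairs$FP,
                           rep_$pairs$FN, rep_$pairs$TN)))
  expect_equal(rep_$mean_accuracy, mean(rep_$pairs$accuracy))
  expect_true(rep_$mean_accuracy >= 0 && rep_$mean_accuracy <= 1)
})

test_that("LOOCV mean accuracy is invariant to trial order", {
  sub <- make_subject(n_pos = 4, n_neg = 3, seed = 6)
  rep1 <- loocv_template_evaluation(sub$trials, "dtw", 5,
                                    channel = sub$cfg$signal_channel)
  shuffled <- sub$trials
  set.seed(99)
  shuffled$trials <- shuffled$trials[sample(seq_along(shuffled$trials))]
  rep2 <- loocv_template_evaluation(shuffled, "dtw", 5,
                                    channel = sub$cfg$signal_channel)
  expect_equal(rep1$mean_accuracy, rep2$mean_accuracy, tolerance = 1e-12)
  expect_identical(rep1$n_pairs, rep2$n_pairs)
})

test_that("LOOCV validates degenerate inputs", {
  sub <- make_subject(n_pos = 2, n_neg = 2, seed = 7)
  only_pos <- sub$trials
  only_pos$trials <- only_pos$trials[trial_labels(only_pos) == "positive"]
  expect_error(loocv_template_evaluation(only_pos, "dtw", 5, channel = "FP1"),
               "positive and .* negative")
  tiny <- sub$trials
  tiny$trials <- tiny$trials[c(1, 3)]  # one of each class, no test trials
  expect_error(loocv_template_evaluation(tiny, "dtw", 5, channel = "FP1"),
               "at least 3")
  expect_error(loocv_template_evaluation(sub$trials, "dtw", 5),
               "exactly one of")
})

test_that("region-mode LOOCV fuses the configured region channels", {
  occ <- region_map_default()$Occipital
  sub <- make_subject(n_pos = 3, n_neg = 2, seed = 8, n_channels = 5,
                      channels = occ, signal_channel = "O1")
  rep_ <- loocv_template_evaluation(sub$trials, "dtw", 5, region = "Occipital")
  expect_identical(rep_$n_pairs, 6L)
  expect_identical(rep_$config$region, "Occipital")
})

test_that("grid search returns the argmax cell with deterministic tie-breaks", {
  sub <- make_subject(n_pos = 4, n_neg = 3, seed = 9)
  best <- grid_search_best(sub$trials, "dtw", 5)
  expect_identical(best$channel, sub$cfg$signal_channel)
  expect_identical(best$segment_start, 0)
  expect_identical(nrow(best$grid), 1L)
  # montage order resolves exact ties: FP1 precedes AF3 in the montage
  g <- best$grid
  expect_true(all(c("channel", "segment_start", "mean_accuracy") %in% names(g)))
})

test_that("grid search recovers a planted signal channel", {
  sub <- make_subject(n_pos = 6, n_neg = 4, seed = 10, trial_s = 10,
                      n_channels = 3, signal_channel = "AF3")
  best <- grid_search_best(sub$trials, "dtw", 5)
  expect_identical(best$channel, "AF3")
  expect_identical(nrow(best$grid), 6L)  # 3 channels x 2 segments
})

test_that("ANOVA feature screen: identical groups, separated groups, planted effect", {
  out <- anova_feature_screen(c(1, 2, 3, 1, 2, 3),
                              rep(c("a", "b"), each = 3))
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)
  set.seed(11)
  g1 <- rnorm(20, 0, 0.01)
  g2 <- rnorm(20, 10, 0.01)
  out2 <- anova_feature_screen(c(g1, g2), rep(c("a", "b"), each = 20))
  expect_lt(out2$p, 1e-6)
  # matches the closed-form F of a linear model fit
  y <- c(rnorm(10), rnorm(10, 1))
  g <- rep(c("a", "b"), each = 10)
  ref <- anova(lm(y ~ g))
  out3 <- anova_feature_screen(y, g)
  expect_equal(out3$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(out3$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_warning(anova_feature_screen(c(0, 0, 1, 1), c("a", "a", "b", "b")),
                 "within-group")
})

test_that("ANOVA screen separates planted BREM features across classes", {
  sub <- make_subject(n_pos = 8, n_neg = 8, seed = 12)
  se_gamma <- vapply(seq_along(sub$trials$trials), function(k) {
    sig <- segment_trial(trial_signal(sub$trials, k, sub$cfg$signal_channel), 5, 0)
    rs <- decompose_rhythms(sig)
    sample_entropy(rs$gamma)
  }, numeric(1))
  out <- anova_feature_screen(se_gamma, trial_labels(sub$trials))
  expect_lte(out$p, 0.05)
})
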