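test_that("confusion counts tally the positive (fatigued) class", {
  cc <- confusion_counts(rep(c(1, 0), c(10, 10)), rep(c(1, 0), c(10, 10)))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 10L, TN = 10L, FP = 0L, FN = 0L))
  # all-positive predictor
  cc2 <- confusion_counts(rep(c(1, 0), c(33, 75)), rep(1, 108))
  expect_equal(unclass(cc2)[c("TP", "FP", "TN", "FN")],
               list(TP = 33L, FP = 75L, TN = 0L, FN = 0L))
  # random predictions vs independent tally loop
  for (seed in 1:5) {
    tp <- eegfatigue:::with_seed(seed, list(t = rbinom(50, 1, 0.4),
                                            p = rbinom(50, 1, 0.5)))
    expect_equal(unclass(confusion_counts(tp$t, tp$p))[c("TP", "FP", "TN", "FN")],
                 oracle_confusion(tp$t, tp$p)[c("TP", "FP", "TN", "FN")],
                 ignore_attr = TRUE)
  }
  expect_error(confusion_counts(integer(0), integer(0)), "at least one")
})

test_that("metrics and Score reproduce the published worked example", {
  # pooled counts TP=30, FN=3, TN=42, FP=33 at w=0.8
  m <- compute_metrics(list(TP = 30, FN = 3, TN = 42, FP = 33), w = 0.8)
  expect_equal(m$recall, 30 / 33)
  expect_equal(round(m$recall * 100), 91)
  expect_equal(m$specificity, 42 / 75)
  expect_equal(round(m$specificity * 100), 56)
  expect_equal(m$accuracy, 72 / 108)
  expect_equal(round(m$accuracy, 2), 0.67)
  expect_equal(m$f1, 60 / 96)
  expect_equal(m$score, (0.8 * 30 / 33 + 0.2 * 42 / 75) * 100)
  expect_equal(m$score_rounded, 84)
})

test_that("Score identities and monotonicity hold", {
  m <- compute_metrics(list(TP = 30, FN = 3, TN = 42, FP = 33), w = 1)
  expect_equal(m$score, 100 * m$recall)
  m0 <- compute_metrics(list(TP = 30, FN = 3, TN = 42, FP = 33), w = 0)
  expect_equal(m0$score, 100 * m0$specificity)
  expect_equal(compute_metrics(list(TP = 5, FN = 0, TN = 7, FP = 0), w = 0.8)$score, 100)
  # published ablation rows recomputed from printed recall/specificity pairs
  expect_equal(round_trip <- compute_metrics(list(TP = 94, FN = 6, TN = 37, FP = 63),
                                             w = 0.8)$score_rounded, 83)
  # non-decreasing in TP (FN+TP fixed) and TN (FP+TN fixed)
  s <- vapply(0:33, function(tp)
    compute_metrics(list(TP = tp, FN = 33 - tp, TN = 42, FP = 33), 0.8)$score,
    numeric(1))
  expect_true(all(diff(s) >= 0))
  s2 <- vapply(0:75, function(tn)
    compute_metrics(list(TP = 30, FN = 3, TN = tn, FP = 75 - tn), 0.8)$score,
    numeric(1))
  expect_true(all(diff(s2) >= 0))
  expect_true(all(s >= 0 & s <= 100))
  # undefined rates flagged, Score withheld
  und <- compute_metrics(list(TP = 0, FN = 0, TN = 5, FP = 5), 0.8)
  expect_true(is.na(und$recall))
  expect_true(is.na(und$score))
})

test_that("channel combination enumeration is exhaustive and ordered", {
  combos <- enumerate_channel_combos(eeg_channels())
  expect_length(combos, 15)
  expect_length(enumerate_channel_combos("TP9"), 1)
  for (k in 1:6) {
    chs <- paste0("C", seq_len(k))
    got <- enumerate_channel_combos(chs)
    expect_length(got, 2^k - 1)
    # independent enumeration via binary masks
    masks <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    ref <- apply(masks[-1, , drop = FALSE], 1, function(m) chs[unlist(m)])
    expect_setequal(vapply(got, paste, "", collapse = "+"),
                    vapply(ref, paste, "", collapse = "+"))
  }
  expect_equal(vapply(combos[1:4], identity, character(1)), eeg_channels())
  expect_error(enumerate_channel_combos(character(0)), "between 1 and 8")
})

fake_result <- function(label, score, recall = 0.5, n = NULL) {
  combo <- strsplit(label, "+", fixed = TRUE)[[1]]
  s <- score / 100
  structure(list(combo = combo, label = label,
                 metrics = list(accuracy = 0.5, f1 = 0.5, recall = recall,
                                specificity = 0.5, score = score,
                                score_rounded = round(score))),
            class = "combo_result")
}

test_that("ranking is by Score with recall / size / label tie-breaks", {
  r <- list(fake_result("AF7", 80), fake_result("TP9+AF7", 84),
            fake_result("TP10", 79))
  rk <- rank_combos(r)
  expect_equal(rk$channels, c("TP9+AF7", "AF7", "TP10"))
  expect_equal(rk$rank, 1:3)
  # equal Score and recall: fewer channels first
  r2 <- list(fake_result("TP9+AF7+AF8+TP10", 84, 0.9),
             fake_result("TP9+AF7+TP10", 84, 0.9))
  expect_equal(rank_combos(r2)$channels[1], "TP9+AF7+TP10")
  # equal Score: higher recall first
  r3 <- list(fake_result("AF7", 84, 0.80), fake_result("TP9", 84, 0.95))
  expect_equal(rank_combos(r3)$channels[1], "TP9")
  # permutation invariance
  r4 <- list(fake_result("AF7", 73, 0.6), fake_result("TP9", 91, 0.9),
             fake_result("AF8", 55, 0.2), fake_result("TP9+AF7", 91, 0.9))
  rk_a <- rank_combos(r4)
  rk_b <- rank_combos(rev(r4))
  expect_identical(rk_a, rk_b)
})

test_that("combo evaluation restricts features and is deterministic", {
  tab <- separable_table(n_subjects = 4, seed = 12)
  res <- evaluate_combo(c("TP9", "AF7"), tab, "svm",
                        list(C = 1, kernel = "linear"), seed = 4)
  expect_s3_class(res, "combo_result")
  expect_equal(res$label, "TP9+AF7")
  expect_length(feature_columns(res$combo), 32) # 16 x 2 presented to the model
  res2 <- evaluate_combo(c("TP9", "AF7"), tab, "svm",
                         list(C = 1, kernel = "linear"), seed = 4)
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$counts, res2$counts)
  expect_error(evaluate_combo("AF8", tab, "svm", list(C = 1, kernel = "linear")),
               "lacks columns")
})

test_that("feature-group ablation covers the seven canonical configurations", {
  tab <- separable_table(n_subjects = 4, seed = 13)
  ab <- ablate_feature_groups(c("TP9", "AF7"), tab, "logistic",
                              list(C = 1, penalty = "l2"), seed = 5)
  expect_equal(nrow(ab), 7)
  expect_equal(ab$feature_group,
               c("All Features", "Statistical", "Frequency", "Entropy",
                 "Entropy + Frequency", "Entropy + Statistical",
                 "Statistical + Frequency"))
  expect_equal(ab$n_features[ab$feature_group == "All Features"], 32)
  expect_equal(ab$n_features[ab$feature_group == "Statistical"], 8)
  expect_equal(ab$n_features[ab$feature_group == "Entropy"], 14)
  expect_equal(ab$n_features[ab$feature_group == "Frequency"], 10)
  expect_true(all(ab$score >= 0 & ab$score <= 100, na.rm = TRUE))
})

test_that("task stratification conserves pooled counts", {
  for (seed in 1:5) {
    preds <- eegfatigue:::with_seed(seed, data.frame(
      truth = rbinom(60, 1, 0.3), pred = rbinom(60, 1, 0.5),
      context = sample(c("baseline", "physical", "mental"), 60, replace = TRUE)))
    st <- stratify_by_task(preds)
    for (fld in c("TP", "FP", "TN", "FN")) {
      expect_equal(st$pooled[[fld]],
                   st$baseline[[fld]] + st$physical[[fld]] + st$mental[[fld]])
    }
    # per-context tallies match an independent group-by loop
    for (ctx in c("baseline", "physical", "mental")) {
      sel <- preds$context == ctx
      expect_equal(unclass(st[[ctx]])[c("TP", "FP", "TN", "FN")],
                   oracle_confusion(preds$truth[sel], preds$pred[sel]),
                   ignore_attr = TRUE)
    }
  }
  # perfectly predicted physical positives leave no physical FN
  p <- data.frame(truth = c(1, 1, 0, 1), pred = c(1, 1, 0, 0),
                  context = c("physical", "physical", "physical", "mental"))
  expect_equal(stratify_by_task(p)$physical$FN, 0)
  expect_error(stratify_by_task(data.frame(truth = 1, pred = 1)), "context")
})
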