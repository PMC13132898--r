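# Evaluation: confusion counts pooled over LOSO folds, the cost-weighted
# Score = (w r + (1 - w) s) x 100, enumeration + evaluation + ranking of all
# channel combinations, feature-group ablation and per-task stratification.

#' Pooled confusion counts
#'
#' Positive class is the fatigued state (label 1).
#'
#' @param truth,pred Binary 0/1 vectors (e.g. pooled over all LOSO folds).
#' @return Object of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (!length(truth)) stop_ef("confusion counts need at least one prediction")
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  structure(
    list(TP = sum(truth == 1 & pred == 1), FP = sum(truth == 0 & pred == 1),
         TN = sum(truth == 0 & pred == 0), FN = sum(truth == 1 & pred == 0)),
    class = "confusion_counts"
  )
}

#' Classification metrics including the cost-weighted Score
#'
#' `accuracy = (TP + TN) / total`, `recall = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`, `F1 = 2 TP / (2 TP + FP + FN)` and
#' `Score = (w * recall + (1 - w) * specificity) x 100` with default
#' `w = 0.8`, weighting missed fatigue more heavily than false alarms. The
#' displayed/ranked Score is rounded half-away-from-zero to an integer
#' (`score_rounded`); the unrounded value is retained. A zero denominator
#' makes the affected rate (and the Score) `NA`.
#'
#' @param counts A [confusion_counts()] (or list with TP/FP/TN/FN).
#' @param w Recall weight in `[0, 1]`.
#' @return List of class `metric_set`: `accuracy`, `f1`, `recall`,
#'   `specificity`, `score`, `score_rounded`, `w`, `counts`.
#' @export
compute_metrics <- function(counts, w = 0.8) {
  check_number(w, "w", lower = 0)
  if (w > 1) stop_ef("w must be <= 1")
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(all(c(TP, FP, TN, FN) >= 0))
  total <- TP + FP + TN + FN
  if (total == 0) stop_ef("empty confusion counts")
  r <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  s <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  score <- if (is.na(r) || is.na(s)) NA_real_ else (w * r + (1 - w) * s) * 100
  structure(
    list(accuracy = (TP + TN) / total, f1 = f1, recall = r, specificity = s,
         score = score, score_rounded = round_half_away(score), w = w,
         counts = counts),
    class = "metric_set"
  )
}

round_half_away <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_real_)
  sign(x) * floor(abs(x) + 0.5)
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.2f | F1 %.2f | recall %.2f | specificity %.2f | Score %.1f (%.0f) [w=%.1f]\n",
              x$accuracy, x$f1, x$recall, x$specificity, x$score,
              x$score_rounded, x$w))
  invisible(x)
}

#' Enumerate all non-empty channel subsets
#'
#' Deterministic order: by subset size, then lexicographically within size
#' (in the montage's fixed channel order).
#'
#' @param channels Character vector of 1-8 channel names.
#' @return List of character vectors (`2^k - 1` subsets).
#' @export
enumerate_channel_combos <- function(channels = eeg_channels()) {
  k <- length(channels)
  if (k < 1L || k > 8L) stop_ef("need between 1 and 8 channels")
  out <- list()
  for (size in seq_len(k)) {
    cmb <- combn(channels, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

combo_label <- function(combo) paste(combo, collapse = "+")

#' Evaluate one channel combination under LOSO
#'
#' Restricts the modelling table to the combination's `16 x |combo|` feature
#' columns and runs full LOSO with training-fold SMOTE using the frozen
#' classifier configuration, pooling confusion counts over folds.
#'
#' @param combo Character vector of channels.
#' @param table A [build_modelling_table()] built with (at least) these
#'   channels.
#' @param family,params Frozen classifier family/hyperparameters from the
#'   modelling stage.
#' @param w Score weight.
#' @param seed Integer seed.
#' @return List of class `combo_result`: `combo`, `label`, `counts`,
#'   `metrics`, `predictions`.
#' @export
evaluate_combo <- function(combo, table, family, params, w = 0.8, seed = 1L) {
  cols <- feature_columns(combo)
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop_ef("table lacks columns: %s", paste(missing, collapse = ", "))
  preds <- loso_predict(table, family, params, feature_cols = cols, seed = seed)
  ok <- !is.na(preds$pred)
  cc <- confusion_counts(preds$truth[ok], preds$pred[ok])
  structure(
    list(combo = combo, label = combo_label(combo), counts = cc,
         metrics = compute_metrics(cc, w = w), predictions = preds),
    class = "combo_result"
  )
}

#' Rank channel-combination results by Score
#'
#' Descending by unrounded Score; ties broken by recall, then by fewer
#' channels, then lexicographically by label. Input order never matters.
#'
#' @param results List of `combo_result`s.
#' @param w Score weight used for display (results already carry metrics).
#' @return data.frame: one row per combination with `rank`, `channels`,
#'   `n_channels`, `accuracy`, `f1`, `recall`, `specificity`, `score`
#'   (unrounded) and `score_rounded` - the heatmap table.
#' @export
rank_combos <- function(results, w = 0.8) {
  stopifnot(length(results) >= 1L)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(channels = r$label, n_channels = length(r$combo),
               accuracy = r$metrics$accuracy, f1 = r$metrics$f1,
               recall = r$metrics$recall, specificity = r$metrics$specificity,
               score = r$metrics$score, score_rounded = r$metrics$score_rounded,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$score, -tab$recall, tab$n_channels, tab$channels)
  tab <- tab[ord, ]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Feature-group ablation for one channel combination
#'
#' Evaluates the seven canonical configurations (three single groups, the
#' three pairwise unions, all features) under the identical LOSO + SMOTE
#' protocol and frozen classifier configuration.
#'
#' @inheritParams evaluate_combo
#' @return data.frame with one row per configuration (`feature_group`,
#'   `n_features`, metrics, Score).
#' @export
ablate_feature_groups <- function(combo, table, family, params, w = 0.8,
                                  seed = 1L) {
  configs <- list(
    "All Features" = "all",
    "Statistical" = "statistical",
    "Frequency" = "frequency",
    "Entropy" = "entropy",
    "Entropy + Frequency" = c("entropy", "frequency"),
    "Entropy + Statistical" = c("entropy", "statistical"),
    "Statistical + Frequency" = c("statistical", "frequency")
  )
  out <- lapply(names(configs), function(nm) {
    cols <- feature_columns(combo, configs[[nm]])
    preds <- loso_predict(table, family, params, feature_cols = cols, seed = seed)
    ok <- !is.na(preds$pred)
    m <- compute_metrics(confusion_counts(preds$truth[ok], preds$pred[ok]), w = w)
    data.frame(feature_group = nm, n_features = length(cols),
               accuracy = m$accuracy, f1 = m$f1, recall = m$recall,
               specificity = m$specificity, score = m$score,
               score_rounded = m$score_rounded, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Stratify pooled predictions by task context
#'
#' Splits held-out predictions into baseline / physical / mental contexts and
#' tallies a confusion matrix per context plus the pooled one (which equals
#' the element-wise sum across contexts).
#'
#' @param predictions Prediction data.frame (from [loso_predict()] or a
#'   `combo_result`) with `truth`, `pred`, `context`.
#' @return Named list of `confusion_counts`: `pooled`, `baseline`,
#'   `physical`, `mental` (contexts absent from the data are omitted).
#' @export
stratify_by_task <- function(predictions) {
  if (inherits(predictions, "combo_result")) predictions <- predictions$predictions
  if (is.null(predictions$context) || anyNA(predictions$context)) {
    stop_ef("predictions lack context tags")
  }
  ok <- !is.na(predictions$pred)
  predictions <- predictions[ok, , drop = FALSE]
  out <- list(pooled = confusion_counts(predictions$truth, predictions$pred))
  for (ctx in intersect(c("baseline", "physical", "mental"),
                        unique(predictions$context))) {
    sel <- predictions$context == ctx
    out[[ctx]] <- confusion_counts(predictions$truth[sel], predictions$pred[sel])
  }
  out
}
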