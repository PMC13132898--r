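# Labelling: derive fatigue thresholds from the cohort's subjective scores
# and assemble the binary-labelled modelling table (one row per subject x
# session x task event s1/s2/s3, feature blocks concatenated per channel).

#' Derive a fatigue threshold from subjective scores
#'
#' Arithmetic mean of the selected scores. The physical threshold averages
#' all participants' physical-task (s2) scores of session 3 (the
#' high-intensity day); the mental threshold averages all mental-task (s3)
#' scores across all three sessions (the mental protocol does not change
#' between sessions).
#'
#' @param scores data.frame with columns `subject`, `session`, `event`,
#'   `score` (as produced by [generate_scores()]/[generate_cohort()]).
#' @param event Event selector, e.g. `"s2"`.
#' @param sessions Integer vector of sessions to include (default: all
#'   present).
#' @return The threshold (numeric scalar).
#' @export
derive_threshold <- function(scores, event, sessions = unique(scores$session)) {
  sel <- scores$event == event & scores$session %in% sessions
  if (!any(sel)) {
    stop_ef("threshold error: no scores for event '%s' in sessions %s",
            event, paste(sessions, collapse = ","))
  }
  mean(scores$score[sel])
}

#' Label policy: thresholds and the inclusive >= rule
#'
#' Thresholds may be pinned (the reference study used 45 for physical and 36
#' for mental fatigue) or derived from a score table via [derive_threshold()].
#' The baseline (s1) rows are labelled against the minimum of the two
#' thresholds (configurable), since with realistic baseline scores this
#' yields the non-fatigued label.
#'
#' @param physical_threshold,mental_threshold Numeric thresholds, or `NULL`
#'   to derive from data in [build_modelling_table()].
#' @param baseline_rule How baseline rows are thresholded: `"min"` (default,
#'   min of the two thresholds), `"physical"` or `"mental"`.
#' @return Object of class `label_policy`.
#' @export
label_policy <- function(physical_threshold = NULL, mental_threshold = NULL,
                         baseline_rule = c("min", "physical", "mental")) {
  baseline_rule <- match.arg(baseline_rule)
  for (th in list(physical_threshold, mental_threshold)) {
    if (!is.null(th)) check_number(th, "threshold")
  }
  structure(list(physical_threshold = physical_threshold,
                 mental_threshold = mental_threshold,
                 baseline_rule = baseline_rule),
            class = "label_policy")
}

#' Binary fatigue label from a score
#'
#' `1` iff `score >= threshold` (inclusive at the boundary).
#'
#' @param score,threshold Finite numerics (vectorised over `score`).
#' @return Integer 0/1 vector.
#' @export
assign_label <- function(score, threshold) {
  stopifnot(all(is.finite(score)), is.finite(threshold))
  as.integer(score >= threshold)
}

#' Build the labelled modelling table
#'
#' One row per (subject, session, task event in s1/s2/s3): the per-channel
#' 16-feature blocks concatenated in fixed channel order (columns named
#' `<channel>_<feature>`), the binary fatigue label from the subjective score
#' against the applicable threshold, and the task `context`
#' (baseline/physical/mental) for later stratification. Rows with a missing
#' score are excluded with a logged warning.
#'
#' @param feature_table Long feature table from [cohort_feature_table()]
#'   (one row per subject, session, channel, event).
#' @param scores Score table (`subject`, `session`, `event`, `score`).
#' @param policy A [label_policy()]; `NULL` thresholds are derived from
#'   `scores` (physical: s2 scores of the highest session; mental: s3 scores
#'   of all sessions).
#' @param channels Channel set to include, in any subset of
#'   [eeg_channels()]; defaults to all four.
#' @return data.frame of class `modelling_table` with key columns `subject`,
#'   `session`, `event`, `context`, `score`, `label` followed by
#'   `16 x length(channels)` feature columns. Attributes `channels` and
#'   `thresholds` record the configuration.
#' @export
build_modelling_table <- function(feature_table, scores,
                                  policy = label_policy(),
                                  channels = eeg_channels()) {
  stopifnot(all(channels %in% eeg_channels()), length(channels) >= 1L)
  channels <- eeg_channels()[eeg_channels() %in% channels]

  phys_th <- policy$physical_threshold
  if (is.null(phys_th)) {
    phys_th <- derive_threshold(scores, "s2", max(scores$session))
  }
  ment_th <- policy$mental_threshold
  if (is.null(ment_th)) {
    ment_th <- derive_threshold(scores, "s3")
  }
  base_th <- switch(policy$baseline_rule,
                    min = min(phys_th, ment_th),
                    physical = phys_th,
                    mental = ment_th)
  context_of <- c(s1 = "baseline", s2 = "physical", s3 = "mental")
  th_of <- c(s1 = base_th, s2 = phys_th, s3 = ment_th)

  task_events <- c("s1", "s2", "s3")
  ft <- feature_table[feature_table$event %in% task_events, , drop = FALSE]
  keys <- unique(ft[, c("subject", "session", "event")])
  keys <- keys[order(keys$subject, keys$session, match(keys$event, task_events)), ]

  dropped <- 0L
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sc <- scores$score[scores$subject == k$subject &
                         scores$session == k$session & scores$event == k$event]
    if (length(sc) != 1L || !is.finite(sc)) {
      dropped <- dropped + 1L
      next
    }
    blocks <- lapply(channels, function(ch) {
      fr <- ft[ft$subject == k$subject & ft$session == k$session &
                 ft$event == k$event & ft$channel == ch, feature_names(),
               drop = FALSE]
      if (nrow(fr) != 1L) {
        stop_ef("feature table has %d rows for %s/%s/%s/%s (expected 1)",
                nrow(fr), k$subject, k$session, k$event, ch)
      }
      v <- as.numeric(fr[1, ])
      names(v) <- paste(ch, feature_names(), sep = "_")
      v
    })
    rows[[i]] <- cbind(
      data.frame(subject = k$subject, session = k$session, event = k$event,
                 context = unname(context_of[k$event]), score = sc,
                 label = assign_label(sc, th_of[[k$event]]),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(unlist(blocks)))
    )
  }
  if (dropped > 0L) {
    ef_log("warn", "build_modelling_table: %d row(s) excluded for missing scores",
           dropped)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "channels") <- channels
  attr(out, "thresholds") <- c(physical = phys_th, mental = ment_th,
                               baseline = base_th)
  class(out) <- c("modelling_table", class(out))
  out
}

#' Feature column names of a modelling table
#'
#' @param channels Channel subset.
#' @param groups Feature-group selection: `"all"` or a character vector of
#'   group names (see [feature_groups()]).
#' @return Character vector of `<channel>_<feature>` column names.
#' @export
feature_columns <- function(channels, groups = "all") {
  feats <- if (identical(groups, "all")) {
    feature_names()
  } else {
    gr <- feature_groups()
    unknown <- setdiff(groups, names(gr))
    if (length(unknown)) stop_ef("unknown feature group(s): %s",
                                 paste(unknown, collapse = ", "))
    feature_names()[feature_names() %in% unlist(gr[groups])]
  }
  as.vector(vapply(channels, function(ch) paste(ch, feats, sep = "_"),
                   character(length(feats))))
}
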