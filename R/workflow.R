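# Orchestration: one validated configuration object and an end-to-end
# pipeline (simulate -> segment/extract -> label -> select classifier ->
# rank channel combinations -> ablate), writing diffable artifacts.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. All defaulted fields are
#' echoed into the emitted effective-config so runs are self-describing.
#'
#' @param n_subjects Cohort size (>= 2; default 12).
#' @param sessions Which of the three protocol sessions (1 low, 2 medium,
#'   3 high intensity) to simulate; default all three.
#' @param s3_duration_s Mental-task duration per session (default 540 s).
#' @param gain_mean,gain_sd,noise_scale,channel_gains Cohort heterogeneity
#'   parameters; see [cohort_profiles()].
#' @param master_seed Integer master seed fanned out to every random
#'   consumer via [derive_seed()].
#' @param feature_params A [feature_params()].
#' @param windows_per_event Cap on windows per event for feature extraction
#'   (`Inf` = all; finite values are a compute-budget subsample).
#' @param policy A [label_policy()] (`NULL` thresholds are derived from the
#'   cohort's scores).
#' @param families Classifier families entering base-classifier selection.
#' @param grids Optional named list of custom candidate grids per family
#'   (default: the full published grids from [model_grid()]).
#' @param w Score weight on recall (default 0.8).
#' @param out_dir Optional output directory for artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_subjects = 12, sessions = 1:3, s3_duration_s = 540,
                       gain_mean = 1, gain_sd = 0.4, noise_scale = 1,
                       channel_gains = c(TP9 = 1, AF7 = 1, AF8 = 0.2, TP10 = 0.2),
                       master_seed = 1,
                       feature_params = eegfatigue::feature_params(),
                       windows_per_event = Inf,
                       policy = label_policy(),
                       families = c("logistic", "boosting", "svm"),
                       grids = NULL, w = 0.8, out_dir = NULL) {
  stopifnot(inherits(feature_params, "feature_params"),
            inherits(policy, "label_policy"),
            all(families %in% c("logistic", "boosting", "svm")))
  check_number(n_subjects, "n_subjects", lower = 2)
  check_number(w, "w", lower = 0)
  sessions <- as.integer(sessions)
  stopifnot(length(sessions) >= 1L, all(sessions %in% 1:3), !anyDuplicated(sessions))
  structure(
    list(n_subjects = as.integer(n_subjects), sessions = sessions,
         s3_duration_s = s3_duration_s,
         gain_mean = gain_mean, gain_sd = gain_sd, noise_scale = noise_scale,
         channel_gains = channel_gains, master_seed = as.integer(master_seed),
         feature_params = feature_params,
         windows_per_event = windows_per_event, policy = policy,
         families = families, grids = grids, w = w, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full pipeline
#'
#' Executes simulate -> extract -> label -> select-classifier -> rank ->
#' stratify -> ablate and returns a report; identical configs give identical
#' reports (timestamps live only in logs). Stages can be truncated with
#' `until` (e.g. `"label"` stops after the modelling table, skipping model
#' training).
#'
#' @param config A [run_config()].
#' @param until Last stage to execute: one of `"extract"`, `"label"`,
#'   `"train"`, `"rank"`, `"ablate"` (default, i.e. everything).
#' @return List of class `run_report` with (up to) `config_echo`, `manifest`,
#'   `feature_table`, `modelling_table`, `thresholds`, `selection`,
#'   `ranking`, `confusion`, `ablation`.
#' @export
run_pipeline <- function(config = run_config(),
                         until = c("ablate", "rank", "train", "label", "extract")) {
  stopifnot(inherits(config, "run_config"))
  until <- match.arg(until)
  stage_no <- match(until, c("extract", "label", "train", "rank", "ablate"))

  cohort <- generate_cohort(
    n_subjects = config$n_subjects,
    plans = default_session_plans(config$s3_duration_s)[config$sessions],
    master_seed = config$master_seed,
    gain_mean = config$gain_mean, gain_sd = config$gain_sd,
    noise_scale = config$noise_scale, channel_gains = config$channel_gains
  )
  ef_log("info", "simulate: cohort of %d subjects x %d sessions",
         config$n_subjects, length(cohort$plans))
  feats <- cohort_feature_table(cohort, config$feature_params,
                                config$windows_per_event)
  report <- list(config_echo = config, manifest = cohort$manifest,
                 feature_table = feats)
  class(report) <- "run_report"
  if (stage_no < 2) return(finish_report(report, config))

  table <- build_modelling_table(feats, cohort$scores, config$policy)
  report$modelling_table <- table
  report$thresholds <- attr(table, "thresholds")
  ef_log("info", "label: %d rows, thresholds physical %.1f / mental %.1f",
         nrow(table), report$thresholds[["physical"]], report$thresholds[["mental"]])
  if (stage_no < 3) return(finish_report(report, config))

  searches <- lapply(config$families, function(fam) {
    grid <- if (!is.null(config$grids[[fam]])) config$grids[[fam]] else model_grid(fam)
    grid_search_loso(table, fam, grid = grid, w = config$w,
                     seed = derive_seed(config$master_seed, "grid", fam))
  })
  selected <- select_base_classifier(searches)
  report$selection <- selected$selection
  report$selected_family <- selected$family
  report$selected_params <- selected$best_params
  report$grid_results <- lapply(searches, `[[`, "results")
  names(report$grid_results) <- config$families
  ef_log("info", "train: selected %s", selected$family)
  if (stage_no < 4) return(finish_report(report, config))

  combos <- enumerate_channel_combos(eeg_channels())
  combo_results <- lapply(combos, function(cb) {
    evaluate_combo(cb, table, selected$family, selected$best_params,
                   w = config$w,
                   seed = derive_seed(config$master_seed, "combo", combo_label(cb)))
  })
  report$ranking <- rank_combos(combo_results, w = config$w)
  top <- combo_results[[match(report$ranking$channels[1],
                              vapply(combo_results, `[[`, "", "label"))]]
  report$top_combo <- top$combo
  report$confusion <- stratify_by_task(top)
  if (stage_no < 5) return(finish_report(report, config))

  report$ablation <- ablate_feature_groups(
    top$combo, table, selected$family, selected$best_params, w = config$w,
    seed = derive_seed(config$master_seed, "ablate"))
  finish_report(report, config)
}

finish_report <- function(report, config) {
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a run report's artifacts
#'
#' Feature table, modelling table, ranking and ablation as CSV; manifest,
#' thresholds, selection and confusion matrices as JSON. No timestamps, so
#' reports are diffable.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$feature_table, file.path(dir, "features.csv"), row.names = FALSE)
  if (!is.null(report$modelling_table)) {
    write.csv(report$modelling_table, file.path(dir, "modelling_table.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$ranking)) {
    write.csv(report$ranking, file.path(dir, "ranking.csv"), row.names = FALSE)
  }
  if (!is.null(report$ablation)) {
    write.csv(report$ablation, file.path(dir, "ablation.csv"), row.names = FALSE)
  }
  meta <- list(
    manifest = report$manifest,
    thresholds = as.list(report$thresholds),
    selected_family = report$selected_family,
    selected_params = report$selected_params,
    selection = report$selection,
    confusion = lapply(report$confusion, unclass),
    effective_config = config_echo_list(report$config_echo)
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}

config_echo_list <- function(config) {
  out <- unclass(config)
  out$feature_params <- unclass(out$feature_params)
  out$policy <- unclass(out$policy)
  out$windows_per_event <- if (is.finite(out$windows_per_event)) {
    out$windows_per_event
  } else {
    "all"
  }
  out
}
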