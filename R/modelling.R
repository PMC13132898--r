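# Subject-independent modelling: LOSO folds, training-fold-only SMOTE,
# classifier backends (regularised logistic regression via glmnet, gradient
# boosting and C-SVC implemented in compiled code), exhaustive grid search
# and base-classifier selection.

#' Leave-one-subject-out folds
#'
#' One fold per subject; the fold's test rows are exactly that subject's
#' rows, training rows are everyone else's. Folds partition the table.
#'
#' @param table A data.frame with a `subject` column (e.g. a
#'   [build_modelling_table()] result).
#' @return Named list (one element per subject) of
#'   `list(subject, train, test)` integer row indices.
#' @export
loso_folds <- function(table) {
  subjects <- unique(table$subject)
  if (length(subjects) < 2L) stop_ef("LOSO needs at least 2 subjects")
  out <- lapply(subjects, function(s) {
    test <- which(table$subject == s)
    list(subject = s, train = setdiff(seq_len(nrow(table)), test), test = test)
  })
  names(out) <- subjects
  out
}

#' SMOTE minority oversampling
#'
#' Balances a binary training set by synthesising minority-class rows as
#' convex combinations `x + u (x_nn - x)`, `u ~ U(0, 1)`, between a minority
#' row and one of its `k` nearest minority neighbours (Euclidean distance in
#' feature space). Apply to training folds only. Deterministic per seed.
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param k_neighbors Number of neighbours (default 5; reduced with a warning
#'   when the minority class is smaller than `k + 1`).
#' @param seed Integer seed.
#' @return List `X`, `y`, `synthetic` (logical provenance tag per row;
#'   original rows first).
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (tab[[1]] == tab[[2]]) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  minority <- if (tab[["1"]] < tab[["0"]]) 1L else 0L
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  if (n_min < 2L) stop_ef("oversampling error: minority class has %d member(s)", n_min)
  k <- as.integer(k_neighbors)
  if (n_min <= k) {
    k <- n_min - 1L
    log_once("smote_k", "smote: k_neighbors reduced to %d (minority size %d)",
             k, n_min)
  }
  n_new <- abs(tab[[1]] - tab[[2]])
  Xm <- X[min_idx, , drop = FALSE]
  d2 <- as.matrix(stats::dist(Xm))^2
  nn <- lapply(seq_len(n_min), function(i) order(d2[i, ])[-1][seq_len(k)])
  synth <- with_seed(seed, {
    base <- sample(rep_len(seq_len(n_min), n_new))
    t(vapply(base, function(i) {
      j <- nn[[i]][sample.int(k, 1L)]
      u <- runif(1)
      Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
    }, numeric(ncol(X))))
  })
  if (ncol(X) == 1L) synth <- matrix(synth, ncol = 1L)
  list(
    X = rbind(X, synth),
    y = c(y, rep(minority, n_new)),
    synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new))
  )
}

# --- feature standardisation (training-fold statistics only) ---------------

scale_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}

scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# --- classifier backends ----------------------------------------------------

#' Fit a binary classifier
#'
#' Families: `"logistic"` (glmnet-backed, sklearn-style `C` mapped to
#' `lambda = 1 / (n C)`, `penalty` l1/l2), `"boosting"` (compiled
#' logistic-loss gradient boosting: `learning_rate`, `n_estimators`,
#' `max_depth`) and `"svm"` (compiled C-SVC via SMO: `C`, `kernel`
#' linear/rbf/poly, `gamma`, `coef0`).
#'
#' @param family Classifier family.
#' @param params Named list of hyperparameters (see above).
#' @param X Numeric feature matrix (standardise first; see vignette).
#' @param y Binary 0/1 labels.
#' @return Model object of class `ef_model`.
#' @export
fit_classifier <- function(family = c("logistic", "boosting", "svm"), params,
                           X, y) {
  family <- match.arg(family)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_ef("training data has a single class")
  fit <- switch(family,
    logistic = {
      lam <- 1 / (nrow(X) * params$C)
      alpha <- if (identical(params$penalty, "l1")) 1 else 0
      # a short decreasing path ending at the target lambda stabilises glmnet;
      # small-class warnings are expected at this cohort scale
      suppressWarnings(
        glmnet::glmnet(X, factor(y, levels = c(0L, 1L)), family = "binomial",
                       alpha = alpha, lambda = lam * c(100, 10, 2, 1),
                       standardize = FALSE, thresh = 1e-10))
    },
    boosting = gbm_train_cpp(X, y, params$learning_rate,
                             as.integer(params$n_estimators),
                             as.integer(params$max_depth)),
    svm = svm_train_cpp(X, ifelse(y == 1L, 1, -1), params$C,
                        params$kernel,
                        if (is.null(params$gamma)) 1 else params$gamma,
                        if (is.null(params$coef0)) 0 else params$coef0)
  )
  structure(list(family = family, params = params, fit = fit,
                 lambda = if (family == "logistic") 1 / (nrow(X) * params$C)),
            class = "ef_model")
}

#' Predict binary labels
#'
#' @param object An `ef_model` from [fit_classifier()].
#' @param newdata Numeric feature matrix (same standardisation as training).
#' @param ... Unused.
#' @return Integer 0/1 predictions.
#' @export
predict.ef_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  switch(object$family,
    logistic = {
      p <- predict(object$fit, newx = X, s = object$lambda, type = "response")
      as.integer(p[, 1] >= 0.5)
    },
    boosting = as.integer(gbm_predict_cpp(object$fit, X) >= 0.5),
    svm = as.integer(svm_decision_cpp(object$fit, X) >= 0)
  )
}

# --- LOSO evaluation of one candidate ---------------------------------------

#' LOSO predictions for one classifier configuration
#'
#' For every fold: standardise with training-fold statistics, oversample the
#' training rows with SMOTE (synthetic rows never enter the test set), fit,
#' and predict the held-out subject. Degenerate training folds (a single
#' class even before oversampling) are flagged, not silently scored.
#'
#' @param table A [build_modelling_table()] result.
#' @param family,params Classifier family and hyperparameters
#'   ([fit_classifier()]).
#' @param feature_cols Feature columns to use (default: every
#'   `<channel>_<feature>` column of the table).
#' @param seed Integer seed (fans out per fold).
#' @param k_neighbors SMOTE neighbourhood size.
#' @return data.frame with one row per table row: `subject`, `session`,
#'   `event`, `context`, `truth`, `pred`, `fold_flag`.
#' @export
loso_predict <- function(table, family, params,
                         feature_cols = attr(table, "feature_cols"),
                         seed = 1L, k_neighbors = 5L) {
  if (is.null(feature_cols)) {
    feature_cols <- feature_columns(attr(table, "channels"))
  }
  X <- as.matrix(table[, feature_cols, drop = FALSE])
  y <- table$label
  folds <- loso_folds(table)
  out <- table[, c("subject", "session", "event", "context")]
  out$truth <- y
  out$pred <- NA_integer_
  out$fold_flag <- ""
  for (f in folds) {
    if (length(unique(y[f$train])) < 2L) {
      out$fold_flag[f$test] <- "degenerate_train"
      next
    }
    sc <- scale_fit(X[f$train, , drop = FALSE])
    Xtr <- scale_apply(X[f$train, , drop = FALSE], sc)
    sm <- smote_oversample(Xtr, y[f$train], k_neighbors,
                           seed = derive_seed(seed, "smote", f$subject))
    model <- fit_classifier(family, params, sm$X, sm$y)
    out$pred[f$test] <- predict(model, scale_apply(X[f$test, , drop = FALSE], sc))
  }
  out
}

# --- hyperparameter grids (the published search space) ----------------------

#' Hyperparameter grid for a classifier family
#'
#' The exhaustive search spaces: logistic `C` in 0.1/1/10/100, penalty l1/l2,
#' solver liblinear/lbfgs (16 candidates); boosting learning_rate 0.01/0.1/1,
#' n_estimators 50/100/300, max_depth 3/5/7 (27); svm `C` 0.1/1/5/10, gamma
#' 0.1/1/10, coef0 0/0.5/1, kernel linear/rbf/poly (108). Candidates with
#' invalid combinations (l1 + lbfgs) are marked `valid = FALSE` and skipped;
#' candidates differing only in ignored dimensions (solver; gamma/coef0 on
#' kernels that ignore them) share one fit.
#'
#' @param family `"logistic"`, `"boosting"` or `"svm"`.
#' @return data.frame of candidates with logical `valid` column.
#' @export
model_grid <- function(family = c("logistic", "boosting", "svm")) {
  family <- match.arg(family)
  g <- switch(family,
    logistic = expand.grid(C = c(0.1, 1, 10, 100), penalty = c("l1", "l2"),
                           solver = c("liblinear", "lbfgs"),
                           stringsAsFactors = FALSE),
    boosting = expand.grid(learning_rate = c(0.01, 0.1, 1),
                           n_estimators = c(50, 100, 300),
                           max_depth = c(3, 5, 7)),
    svm = expand.grid(C = c(0.1, 1, 5, 10), gamma = c(0.1, 1, 10),
                      coef0 = c(0.0, 0.5, 1.0),
                      kernel = c("linear", "rbf", "poly"),
                      stringsAsFactors = FALSE)
  )
  g$valid <- if (family == "logistic") {
    !(g$penalty == "l1" & g$solver == "lbfgs") # lbfgs cannot handle l1
  } else {
    TRUE
  }
  g
}

# Canonical (effective) parameter list of a grid row: drops dimensions the
# backend ignores so equivalent candidates share one evaluation.
effective_params <- function(family, row) {
  row <- as.list(row)
  row$valid <- NULL
  if (family == "logistic") row$solver <- NULL
  if (family == "svm") {
    if (row$kernel == "linear") { row$gamma <- NULL; row$coef0 <- NULL }
    if (row$kernel == "rbf") row$coef0 <- NULL
  }
  row
}

#' Exhaustive LOSO grid search for one classifier family
#'
#' Every grid candidate is evaluated by full LOSO with SMOTE inside each
#' training fold. The selection objective is the Score (default weight
#' `w = 0.8`) of the confusion counts pooled over all folds; configurable to
#' `"accuracy"`. All candidate results are retained.
#'
#' @inheritParams loso_predict
#' @param grid Candidate grid (default [model_grid()] for the family).
#' @param w Score weight on recall.
#' @param objective `"score"` (default) or `"accuracy"`.
#' @return List of class `grid_search_result`: `family`, `best_params`,
#'   `best_metrics`, `results` (one row per enumerated candidate with pooled
#'   metrics and `objective`), `n_candidates`.
#' @export
grid_search_loso <- function(table, family, grid = model_grid(family),
                             feature_cols = NULL, w = 0.8,
                             objective = c("score", "accuracy"), seed = 1L,
                             k_neighbors = 5L) {
  objective <- match.arg(objective)
  if (is.null(feature_cols)) feature_cols <- feature_columns(attr(table, "channels"))
  cache <- new.env(parent = emptyenv())
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, , drop = FALSE]
    if (!isTRUE(row$valid)) {
      res[[i]] <- data.frame(candidate = i, skipped = TRUE, objective = NA_real_)
      next
    }
    ep <- effective_params(family, row)
    key <- paste(family, paste(names(ep), unlist(ep), sep = "=", collapse = ";"))
    if (is.null(cache[[key]])) {
      preds <- loso_predict(table, family, ep, feature_cols, seed, k_neighbors)
      ok <- !is.na(preds$pred)
      cc <- confusion_counts(preds$truth[ok], preds$pred[ok])
      met <- compute_metrics(cc, w = w)
      obj <- if (objective == "score") met$score else met$accuracy
      cache[[key]] <- list(metrics = met, objective = obj,
                           flagged = any(preds$fold_flag != ""))
    }
    hit <- cache[[key]]
    res[[i]] <- data.frame(candidate = i, skipped = FALSE,
                           objective = hit$objective,
                           accuracy = hit$metrics$accuracy,
                           f1 = hit$metrics$f1, recall = hit$metrics$recall,
                           specificity = hit$metrics$specificity,
                           score = hit$metrics$score,
                           flagged = hit$flagged)
  }
  results <- cbind(grid[rep(seq_len(nrow(grid)), 1L), , drop = FALSE],
                   do.call(rbind, lapply(res, function(r) {
                     cols <- c("candidate", "skipped", "objective", "accuracy",
                               "f1", "recall", "specificity", "score", "flagged")
                     for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
                     r[, cols]
                   })))
  best_i <- which(results$objective == max(results$objective, na.rm = TRUE))[1]
  best_params <- effective_params(family, grid[best_i, , drop = FALSE])
  structure(
    list(family = family, best_params = best_params,
         best_metrics = results[best_i, c("accuracy", "f1", "recall",
                                          "specificity", "score")],
         results = results, n_candidates = nrow(grid)),
    class = "grid_search_result"
  )
}

#' Select the base classifier among families
#'
#' Families are ranked by accuracy, then F1; remaining ties are broken by
#' recall (the published rule), then by the documented family order
#' (logistic, boosting, svm). Comparison uses values rounded to two decimals
#' (the precision at which the published table reports them), so near-ties
#' resolve the way the printed tie-break does.
#'
#' @param results List of `grid_search_result`s (>= 2 families).
#' @return The winning `grid_search_result`, with `$selection` describing the
#'   ordering.
#' @export
select_base_classifier <- function(results) {
  stopifnot(length(results) >= 2L)
  fam_order <- c("logistic", "boosting", "svm")
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(family = r$family,
               accuracy = round(r$best_metrics$accuracy, 2),
               f1 = round(r$best_metrics$f1, 2),
               recall = round(r$best_metrics$recall, 2),
               stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$accuracy, -tab$f1, -tab$recall, match(tab$family, fam_order))
  winner <- results[[ord[1]]]
  winner$selection <- tab[ord, ]
  winner
}
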