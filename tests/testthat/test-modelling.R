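test_that("LOSO folds partition the table by subject", {
  tab <- data.frame(subject = rep(sprintf("S%02d", 1:12), each = 9))
  folds <- loso_folds(tab)
  expect_length(folds, 12)
  expect_true(all(vapply(folds, function(f) length(f$test), integer(1)) == 9))
  test_union <- sort(unlist(lapply(folds, `[[`, "test"), use.names = FALSE))
  expect_equal(test_union, seq_len(108)) # disjoint cover
  for (f in folds) {
    expect_length(intersect(tab$subject[f$train], tab$subject[f$test]), 0)
    expect_setequal(c(f$train, f$test), seq_len(108))
  }
  expect_length(loso_folds(data.frame(subject = c("A", "A", "B"))), 2)
  expect_error(loso_folds(data.frame(subject = rep("A", 5))), "2 subjects")
})

test_that("SMOTE balances classes by interpolating minority neighbours", {
  X <- matrix(rnorm(28), 14, 2)
  y <- rep(c(0L, 1L), c(10, 4))
  out <- smote_oversample(X, y, k_neighbors = 3, seed = 11)
  expect_equal(as.vector(table(out$y)), c(10, 10))
  expect_equal(sum(out$synthetic), 6)
  expect_false(any(out$synthetic[seq_len(14)]))
  # every synthetic point lies on a segment between two original minority rows
  Xm <- X[y == 1L, , drop = FALSE]
  for (i in which(out$synthetic)) {
    z <- out$X[i, ]
    on_segment <- FALSE
    for (a in 1:3) for (b in 1:4) {
      if (a == b) next
      d <- Xm[b, ] - Xm[a, ]
      u <- if (abs(d[1]) > abs(d[2])) (z[1] - Xm[a, 1]) / d[1] else (z[2] - Xm[a, 2]) / d[2]
      if (is.finite(u) && u > 0 && u < 1 &&
          max(abs(Xm[a, ] + u * d - z)) < 1e-8) on_segment <- TRUE
    }
    expect_true(on_segment)
  }
  # determinism and no-op cases
  out2 <- smote_oversample(X, y, k_neighbors = 3, seed = 11)
  expect_identical(out, out2)
  bal <- smote_oversample(X[1:8, ], rep(c(0L, 1L), 4), seed = 1)
  expect_equal(nrow(bal$X), 8)
  expect_error(smote_oversample(X, rep(c(0L, 1L), c(13, 1)), seed = 1),
               "oversampling error")
  rm(list = ls(eegfatigue:::.log_seen), envir = eegfatigue:::.log_seen)
  expect_message(smote_oversample(X, rep(c(0L, 1L), c(11, 3)), k_neighbors = 5,
                                  seed = 1),
                 "reduced")
})

# Frozen scikit-learn oracle: the fixture below was fitted with sklearn 1.9
# (SVC, GradientBoostingClassifier, LogisticRegression) and the predictions
# on the 24-row test grid recorded. Compiled SVM/boosting backends must
# reproduce them exactly; the l1 logistic backend (different optimiser) must
# agree on all but boundary points.
test_that("classifier backends reproduce the frozen reference predictions", {
  set.seed(2024)
  n <- 40; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(1.5, -2, 0.8, 0, 0.5)
  y <- as.integer(X %*% beta + 0.5 * rnorm(n) > 0)
  Xt <- matrix(rnorm(24 * p), 24, p)
  s <- function(model) paste(predict(model, Xt), collapse = "")

  expect_equal(s(fit_classifier("svm", list(C = 1, kernel = "rbf", gamma = 0.1), X, y)),
               "111101011111111000000110")
  expect_equal(s(fit_classifier("svm", list(C = 0.1, kernel = "linear"), X, y)),
               "111101011111111010000110")
  expect_equal(s(fit_classifier("svm", list(C = 5, kernel = "poly", gamma = 0.5,
                                            coef0 = 0.5), X, y)),
               "111100011110011000000110")
  gbm <- fit_classifier("boosting", list(learning_rate = 0.1, n_estimators = 50,
                                         max_depth = 3), X, y)
  expect_equal(s(gbm), "111101001010111000100010")
  # reference class probabilities, first five test rows
  expect_equal(eegfatigue:::gbm_predict_cpp(gbm$fit, Xt)[1:5],
               c(0.996444, 0.996444, 0.996444, 0.996444, 0.002941),
               tolerance = 1e-5)
  expect_equal(s(fit_classifier("logistic", list(C = 1, penalty = "l2"), X, y)),
               "111101011111111000000110")
  ref_l1 <- strsplit("111101010111111000000010", "")[[1]]
  got_l1 <- predict(fit_classifier("logistic", list(C = 0.1, penalty = "l1"), X, y), Xt)
  expect_gte(mean(got_l1 == as.integer(ref_l1)), 0.85)
  # reference SVM decision values, first five test rows (SMO tolerance)
  rbf <- fit_classifier("svm", list(C = 1, kernel = "rbf", gamma = 0.1), X, y)
  expect_equal(eegfatigue:::svm_decision_cpp(rbf$fit, Xt)[1:5],
               c(1.069945, 0.326540, 0.348332, 0.564026, -0.740712),
               tolerance = 2e-3)
})

test_that("model grids enumerate the published candidate lists", {
  g_svm <- model_grid("svm")
  expect_equal(nrow(g_svm), 108) # 4 x 3 x 3 x 3
  expect_true(all(g_svm$valid))
  expect_setequal(unique(g_svm$C), c(0.1, 1, 5, 10))
  expect_setequal(unique(g_svm$kernel), c("linear", "rbf", "poly"))
  g_lr <- model_grid("logistic")
  expect_equal(nrow(g_lr), 16)
  expect_equal(sum(!g_lr$valid), 4) # l1 + lbfgs skipped
  g_gb <- model_grid("boosting")
  expect_equal(nrow(g_gb), 27)
  # ignored dimensions are dropped from effective parameters
  lin <- eegfatigue:::effective_params("svm",
    data.frame(C = 1, gamma = 10, coef0 = 1, kernel = "linear", valid = TRUE))
  expect_named(lin, c("C", "kernel"))
  rbf <- eegfatigue:::effective_params("svm",
    data.frame(C = 1, gamma = 10, coef0 = 1, kernel = "rbf", valid = TRUE))
  expect_named(rbf, c("C", "gamma", "kernel"))
})

test_that("LOSO predictions never leak subjects or synthetic rows", {
  tab <- separable_table(n_subjects = 5, seed = 3)
  preds <- loso_predict(tab, "logistic", list(C = 1, penalty = "l2"), seed = 9)
  expect_equal(nrow(preds), nrow(tab)) # only original rows are ever scored
  expect_identical(preds$subject, tab$subject)
  expect_identical(preds$truth, tab$label)
  # deterministic per seed
  preds2 <- loso_predict(tab, "logistic", list(C = 1, penalty = "l2"), seed = 9)
  expect_identical(preds, preds2)
})

test_that("grid search finds perfect candidates on separable data", {
  tab <- separable_table(n_subjects = 6, seed = 5)
  grid <- data.frame(C = c(0.1, 1), penalty = "l2", solver = "liblinear",
                     valid = TRUE)
  gs <- grid_search_loso(tab, "logistic", grid = grid, seed = 2)
  expect_equal(gs$n_candidates, 2)
  expect_equal(gs$best_metrics$recall, 1.0)
  expect_equal(gs$best_metrics$score, 100)
  single <- grid_search_loso(tab, "svm",
                             grid = data.frame(C = 1, gamma = 0.1, coef0 = 0,
                                               kernel = "linear", valid = TRUE),
                             seed = 2)
  expect_equal(single$best_params$C, 1)
  expect_equal(single$best_params$kernel, "linear")
})

test_that("base-classifier selection ranks by accuracy, F1, then recall", {
  mk <- function(family, acc, f1, rec) {
    structure(list(family = family,
                   best_params = list(),
                   best_metrics = data.frame(accuracy = acc, f1 = f1,
                                             recall = rec, specificity = 0.5,
                                             score = 0)),
              class = "grid_search_result")
  }
  # the published tie: equal Acc/F1, recall 77 vs 78 -> higher recall wins
  sel <- select_base_classifier(list(mk("logistic", 0.75, 0.73, 0.77),
                                     mk("svm", 0.75, 0.73, 0.78)))
  expect_equal(sel$family, "svm")
  # strict dominance
  sel2 <- select_base_classifier(list(mk("logistic", 0.60, 0.55, 0.9),
                                      mk("boosting", 0.73, 0.68, 0.67),
                                      mk("svm", 0.75, 0.73, 0.78)))
  expect_equal(sel2$family, "svm")
  # three-way exact tie -> documented family order
  sel3 <- select_base_classifier(list(mk("svm", 0.7, 0.7, 0.7),
                                      mk("boosting", 0.7, 0.7, 0.7),
                                      mk("logistic", 0.7, 0.7, 0.7)))
  expect_equal(sel3$family, "logistic")
})

test_that("degenerate training folds are flagged, not scored", {
  tab <- separable_table(n_subjects = 3, seed = 6)
  tab$label <- ifelse(tab$subject == "S01", 1L, 0L) # one subject owns class 1
  preds <- loso_predict(tab, "logistic", list(C = 1, penalty = "l2"), seed = 1)
  s01 <- preds$subject == "S01"
  expect_true(all(preds$fold_flag[s01] == "degenerate_train"))
  expect_true(all(is.na(preds$pred[s01])))
  expect_true(all(!is.na(preds$pred[!s01])))
})
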