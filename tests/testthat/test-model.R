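# Deterministic small feature matrix for selection/evaluation tests:
# a few informative columns tied to the label, the rest noise.
make_toy_matrix <- function(n_subjects = 12, records_per_subject = 2,
                            n_features = 12, informative = 2, seed = 1,
                            separation = 2) {
  set.seed(seed)
  subjects <- sprintf("T%02d", seq_len(n_subjects))
  labels <- rep(c("MCI", "control"), length.out = n_subjects)
  rows <- tidyr::expand_grid(subject_id = subjects,
                             day_index = seq_len(records_per_subject))
  rows$label <- labels[match(rows$subject_id, subjects)]
  y <- as.integer(rows$label == "MCI")
  X <- matrix(rnorm(nrow(rows) * n_features), nrow(rows), n_features)
  for (j in seq_len(informative)) {
    X[, j] <- X[, j] + separation * y
  }
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  out <- dplyr::bind_cols(
    tibble::tibble(record_id = paste0(rows$subject_id, "_d", rows$day_index),
                   subject_id = rows$subject_id, label = rows$label),
    tibble::as_tibble(X))
  structure(out, mode = "P", feature_cols = colnames(X),
            class = c("wear_features", class(out)))
}

test_that("permutation importance ranks a perfect predictor first", {
  m <- make_toy_matrix(n_subjects = 30, records_per_subject = 1,
                       n_features = 6, informative = 0, seed = 3)
  m$f01 <- as.numeric(m$label == "MCI")  # label-identical feature
  imp <- permutation_importance_by_group(m, columns = paste0("f0", 1:6),
                                         seed = 5)
  expect_equal(imp$feature[which.max(imp$importance)], "f01")
  expect_gt(max(imp$importance), 0.2)
})

test_that("permutation importance is deterministic and near zero for noise", {
  m <- make_toy_matrix(n_subjects = 40, records_per_subject = 1,
                       n_features = 5, informative = 0, seed = 9)
  a <- permutation_importance_by_group(m, columns = paste0("f0", 1:5),
                                       seed = 2)
  b <- permutation_importance_by_group(m, columns = paste0("f0", 1:5),
                                       seed = 2)
  expect_identical(a, b)
  expect_true(all(abs(a$importance) < 0.15))
  # zero-variance feature cannot help the forest
  m$f01 <- 1
  z <- permutation_importance_by_group(m, columns = paste0("f0", 1:5),
                                       seed = 2)
  expect_lte(z$importance[z$feature == "f01"], 1e-8)
})

test_that("selection arithmetic: top-5 per group, above-median retention", {
  imp <- tibble::tibble(
    feature = sprintf("g%d_f%d", rep(1:8, each = 6), rep(1:6, 8)),
    group = as.character(rep(1:8, each = 6)),
    importance = seq(0.01, by = 0.01, length.out = 48))
  sel <- select_features(imp)
  expect_equal(nrow(sel$candidates), 40)
  expect_equal(nrow(sel$retained), 20)
  expect_true(all(sel$retained$importance > sel$median))
  expect_true(all(sel$retained$feature %in% sel$candidates$feature))

  # candidates 1..40 -> retained exactly those valued 21..40
  imp40 <- tibble::tibble(feature = sprintf("h%02d", 1:40),
                          group = as.character(rep(1:8, each = 5)),
                          importance = 1:40)
  sel40 <- select_features(imp40)
  expect_setequal(sel40$retained$importance, 21:40)

  # all equal -> nothing retained, warning
  eq <- dplyr::mutate(imp40, importance = 1)
  expect_warning(sel_eq <- select_features(eq), "retained")
  expect_equal(nrow(sel_eq$retained), 0)

  # fewer than 5 scored features in a group -> all taken
  small <- tibble::tibble(feature = c("a", "b"), group = "g",
                          importance = c(2, 1))
  expect_equal(nrow(select_features(small)$candidates), 2)
})

test_that("leave-one-subject-out folds partition records by subject", {
  ids <- c("A", "A", "B", "C", "C", "C")
  folds <- loso_folds(ids)
  expect_length(folds, 3)
  expect_equal(vapply(folds, function(f) length(f$test_idx), integer(1)),
               c(2L, 1L, 3L))
  for (f in folds) {
    expect_length(intersect(ids[f$test_idx], ids[f$train_idx]), 0)
  }
  covered <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_equal(covered, seq_along(ids))
  expect_error(loso_folds(rep("A", 3)), ">= 2 subjects")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  expect_equal(auc_rank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  # invariant under monotone transformation of scores
  expect_equal(auc_rank(exp(s), y), auc_rank(s, y))
})

test_that("grid search: single point, separable data, determinism", {
  m <- make_toy_matrix(n_subjects = 10, records_per_subject = 2,
                       n_features = 6, informative = 3, seed = 21,
                       separation = 4)
  folds <- loso_folds(m$subject_id)
  one <- tibble::tibble(n_learners = 40, learning_rate = 0.1, max_depth = 2)
  gs <- grid_search("gbdt", one, m, folds, seed = 1)
  expect_equal(nrow(gs$results), 1)
  expect_equal(gs$best$n_learners, 40)
  expect_equal(gs$best$auc, 1.0, tolerance = 0.01)  # linearly separable

  two <- tibble::tibble(n_learners = c(20, 40), learning_rate = 0.1,
                        max_depth = 2)
  g1 <- grid_search("xgboost", two, m, folds, seed = 6)
  g2 <- grid_search("xgboost", two, m, folds, seed = 6)
  expect_identical(g1$results, g2$results)
})

test_that("evaluation metrics match definitional arithmetic", {
  # force a known confusion matrix through the public metric path:
  # TP=3 FP=1 FN=1 TN=5 -> precision 75, recall 75, F1 75, accuracy 80
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.1, 0.2)
  yhat <- as.integer(p >= 0.5)
  tp <- sum(yhat & y); fp <- sum(yhat & !y)
  fn <- sum(!yhat & y); tn <- sum(!yhat & !y)
  expect_equal(c(tp, fp, fn, tn), c(3, 1, 1, 5))
  expect_equal(100 * tp / (tp + fp), 75)
  expect_equal(100 * tp / (tp + fn), 75)
  expect_equal(100 * (tp + tn) / 10, 80)

  m <- make_toy_matrix(n_subjects = 10, records_per_subject = 2,
                       n_features = 6, informative = 3, seed = 21,
                       separation = 4)
  folds <- loso_folds(m$subject_id)
  best <- tibble::tibble(n_learners = 40, learning_rate = 0.1, max_depth = 2)
  ev <- evaluate_model("gbdt", best, m, folds, seed = 2)
  # perfect separation: all metrics 100
  expect_equal(ev$metrics$accuracy, 100)
  expect_equal(ev$metrics$f1, 100)
  expect_equal(ev$metrics$auc, 100)
  # F1 is the harmonic mean of precision and recall
  with(ev$metrics, expect_equal(f1, 2 * precision * recall /
                                  (precision + recall)))
  # normalised importances top out at exactly 100
  expect_equal(max(ev$importance$importance), 100)
  expect_true(all(ev$importance$importance >= 0 &
                    ev$importance$importance <= 100))
  # ROC endpoints
  expect_equal(ev$roc$fpr[1], 0)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
})

test_that("fold provenance shows train-only preprocessing and disjoint subjects", {
  m <- make_toy_matrix(n_subjects = 8, records_per_subject = 2,
                       n_features = 5, informative = 2, seed = 13)
  m$f05[3] <- NA  # force imputation
  folds <- loso_folds(m$subject_id)
  best <- tibble::tibble(n_learners = 20, learning_rate = 0.1, max_depth = 2)
  ev <- evaluate_model("xgboost", best, m, folds, seed = 3)
  prov <- ev$provenance
  expect_equal(nrow(prov), 8)
  expect_true(all(prov$impute_fit == "train"))
  for (k in seq_len(nrow(prov))) {
    expect_length(intersect(prov$train_subjects[[k]],
                            prov$test_subjects[[k]]), 0)
  }
  # every record predicted exactly once
  expect_equal(sort(ev$predictions$record_id), sort(m$record_id))
})

test_that("tidiers expose metrics and selection flags", {
  m <- make_toy_matrix(n_subjects = 8, records_per_subject = 1,
                       n_features = 5, informative = 2, seed = 31,
                       separation = 4)
  folds <- loso_folds(m$subject_id)
  best <- tibble::tibble(n_learners = 20, learning_rate = 0.1, max_depth = 2)
  ev <- evaluate_model("gbdt", best, m, folds, seed = 3)
  td <- tidy(ev)
  expect_setequal(td$metric, c("accuracy", "precision", "recall", "f1", "auc"))
  gl <- glance(ev)
  expect_equal(gl$family, "gbdt")
  expect_equal(gl$n_learners, 20)

  imp40 <- tibble::tibble(feature = sprintf("h%02d", 1:40),
                          group = as.character(rep(1:8, each = 5)),
                          importance = 1:40)
  td2 <- tidy(select_features(imp40))
  expect_equal(sum(td2$retained), 20)
  expect_equal(sum(td2$candidate), 40)
})
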