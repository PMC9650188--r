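# Feature selection (random-forest permutation importance), gradient
# boosted classifiers, subject-based leave-one-out evaluation.

feature_cols_of <- function(features) {
  attr(features, "feature_cols") %||%
    setdiff(names(features), c("record_id", "subject_id", "label",
                               "day_index"))
}

label_vector <- function(features) {
  as.integer(features$label == "MCI")
}

stratified_folds <- function(y, k = 10) {
  idx <- seq_along(y)
  folds <- rep(NA_integer_, length(y))
  for (cl in unique(y)) {
    members <- sample(idx[y == cl])
    folds[members] <- rep_len(seq_len(k), length(members))
  }
  folds
}

#' Rank-based area under the ROC curve
#'
#' @param scores Predicted scores (higher = more positive).
#' @param labels 0/1 labels (1 = positive class).
#' @return AUC on [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random-forest permutation importance within a feature group
#'
#' Stratified ten-fold cross-validation at the record level: per fold a
#' random forest is fit on the training rows and permutation importance
#' is computed on the held-out fold with ten random permutation repeats
#' per feature (importance = drop in held-out accuracy). Importances are
#' averaged over repeats and folds. Deterministic for a fixed seed.
#'
#' @param features A `wear_features` matrix (any mode).
#' @param group Group name from [feature_groups()] (`"hr"` ... `"od"`), or
#'   `NULL` to score an explicit `columns` set.
#' @param columns Explicit feature columns (overrides `group`).
#' @param seed Integer seed.
#' @param n_folds,n_repeats,num_trees Cross-validation folds, permutation
#'   repeats and forest size.
#' @return Tibble `feature`, `group`, `importance`.
#' @export
permutation_importance_by_group <- function(features, group = NULL,
                                            columns = NULL, seed = 1,
                                            n_folds = 10, n_repeats = 10,
                                            num_trees = 100) {
  if (is.null(columns)) {
    stopifnot(!is.null(group))
    columns <- feature_groups()$feature[feature_groups()$group == group]
  }
  columns <- intersect(columns, names(features))
  y <- label_vector(features)
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (min(table(y)) < n_folds) {
    abort(sprintf(
      "a class has fewer than %d records; use fewer folds", n_folds))
  }
  X <- as.data.frame(features[, columns, drop = FALSE])
  # median imputation so the forest accepts incomplete windows
  for (cl in names(X)) {
    bad <- is.na(X[[cl]])
    if (any(bad)) X[[cl]][bad] <- median(X[[cl]], na.rm = TRUE)
  }
  imp <- matrix(0, nrow = length(columns), ncol = 0)
  with_seed(seed, {
    fold_id <- stratified_folds(y, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold_id != f
      dtr <- X[tr, , drop = FALSE]
      dtr$.y <- factor(y[tr])
      # probability forest: class-vote ties would otherwise be broken
      # randomly at prediction time, breaking determinism
      rf <- ranger::ranger(.y ~ ., data = dtr, num.trees = num_trees,
                           probability = TRUE,
                           seed = derive_seed(seed, f), num.threads = 1)
      Xte <- X[!tr, , drop = FALSE]
      yte <- y[!tr]
      prob_of_1 <- function(newdata) {
        predict(rf, newdata, num.threads = 1)$predictions[, "1"]
      }
      base_acc <- mean(as.integer(prob_of_1(Xte) >= 0.5) == yte)
      for (r in seq_len(n_repeats)) {
        # stack all single-feature permutations into one prediction call
        stacked <- Xte[rep(seq_len(nrow(Xte)), length(columns)), ,
                       drop = FALSE]
        for (jj in seq_along(columns)) {
          rows <- (jj - 1) * nrow(Xte) + seq_len(nrow(Xte))
          stacked[rows, jj] <- sample(Xte[[jj]])
        }
        pred <- as.integer(prob_of_1(stacked) >= 0.5)
        accs <- colMeans(matrix(pred == rep(yte, length(columns)),
                                nrow = nrow(Xte)))
        imp <- cbind(imp, base_acc - accs)
      }
    }
  })
  tibble::tibble(feature = columns,
                 group = group %||% NA_character_,
                 importance = rowMeans(imp))
}

#' Select features by top-5 per group and above-median retention
#'
#' From each group's importance table the five most important features are
#' selected (ties broken by column order); the candidates from all groups
#' are pooled and only those with importance strictly greater than the
#' candidate-set median are retained. With 8 groups of 5 candidates and
#' distinct importances this yields exactly 20 features.
#'
#' @param importances Tibble `feature`, `group`, `importance` (rows from
#'   [permutation_importance_by_group()] over all groups), or a list of
#'   such tibbles.
#' @param top_k Candidates per group.
#' @return Object of class `wear_selection`: list with `importances`,
#'   `candidates` and `retained` (both tibbles).
#' @export
select_features <- function(importances, top_k = 5) {
  if (is.list(importances) && !is.data.frame(importances)) {
    importances <- dplyr::bind_rows(importances)
  }
  if (!nrow(importances)) abort("empty importance table")
  candidates <- importances |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$.ord,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")
  med <- median(candidates$importance)
  retained <- dplyr::filter(candidates, .data$importance > med)
  if (!nrow(retained)) {
    warn("no candidate importance strictly exceeds the median; nothing retained")
  }
  structure(list(importances = importances, candidates = candidates,
                 retained = retained, median = med),
            class = "wear_selection")
}

#' @export
print.wear_selection <- function(x, ...) {
  cat(sprintf("<wear_selection> %d candidates, %d retained (median importance %.4g)\n",
              nrow(x$candidates), nrow(x$retained), x$median))
  invisible(x)
}

#' Subject-based leave-one-out folds
#'
#' One fold per subject: all of that subject's records form the test set
#' and every other record the training set, so train and test subject
#' sets are disjoint in every fold and the test sets partition the
#' records.
#'
#' @param subject_ids Character vector, one entry per record.
#' @return List of folds, each `list(test_subject, test_idx, train_idx)`.
#' @export
loso_folds <- function(subject_ids) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 2) abort("leave-one-subject-out needs >= 2 subjects")
  lapply(subjects, function(s) {
    list(test_subject = s,
         test_idx = which(subject_ids == s),
         train_idx = which(subject_ids != s))
  })
}

#' Default hyperparameter grid
#' @return Tibble crossing n_learners, learning_rate and max_depth.
#' @export
default_grid <- function() {
  tidyr::expand_grid(n_learners = c(50, 100, 150, 200, 300),
                     learning_rate = c(0.01, 0.05, 0.1),
                     max_depth = c(2, 3, 5))
}

booster_params <- function(family, learning_rate, max_depth) {
  base <- list(objective = "binary:logistic", eta = learning_rate,
               max_depth = max_depth, nthread = 1)
  if (family == "gbdt") {
    # classical gradient boosting: exact greedy splits, no shrinkage-side
    # L1/L2 regularisation
    base <- c(base, list(lambda = 0, alpha = 0, tree_method = "exact",
                         colsample_bytree = 1, subsample = 1))
  }
  base
}

fit_booster <- function(family, params_row, X, y, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  pars <- booster_params(family, params_row$learning_rate,
                         params_row$max_depth)
  # balance the loss to a constant effective class prior: leave-one-subject-
  # out folds otherwise shift the training prior against the held-out class
  # and bias pooled scores (anti-ranking under a label-permuted null)
  if (any(y == 1) && any(y == 0)) {
    pars$scale_pos_weight <- sum(y == 0) / sum(y == 1)
  }
  xgboost::xgb.train(params = pars, data = dtrain,
                     nrounds = params_row$n_learners, verbose = 0)
}

# Impute NA cells with training-row column medians; returns train/test
# matrices plus the provenance of the imputation fit.
impute_train_medians <- function(X, train_idx, test_idx) {
  meds <- vapply(X, function(v) median(v[train_idx], na.rm = TRUE), double(1))
  fill <- function(rows) {
    M <- as.matrix(X[rows, , drop = FALSE])
    for (j in seq_len(ncol(M))) {
      bad <- is.na(M[, j])
      if (any(bad)) M[bad, j] <- meds[j]
    }
    M
  }
  list(train = fill(train_idx), test = fill(test_idx),
       fit_rows = train_idx)
}

# Pooled held-out predictions over LOSO folds.
#
# Training folds are prior-stabilised: besides the held-out subject, one
# random training subject of the opposite class is dropped, so every fold
# trains on the same class composition. Without this the held-out
# subject's class is always under-represented in training, which shifts
# each fold's score level against it and anti-ranks the pooled
# predictions (pooled AUC well below 0.5 on label-permuted data).
loso_predictions <- function(family, params_row, features, folds, seed,
                             columns = NULL) {
  cols <- columns %||% feature_cols_of(features)
  X <- as.data.frame(features[, cols, drop = FALSE])
  y <- label_vector(features)
  subj <- features$subject_id
  preds <- rep(NA_real_, length(y))
  provenance <- purrr::imap_dfr(folds, function(fd, k) {
    test_y <- unique(y[fd$test_idx])[1]
    train_idx <- fd$train_idx
    opp <- unique(subj[train_idx][y[train_idx] != test_y])
    dropped <- character()
    if (length(opp) > 1) {
      dropped <- with_seed(derive_seed(seed, k, 77), sample(opp, 1))
      train_idx <- train_idx[subj[train_idx] != dropped]
    }
    imp <- impute_train_medians(X, train_idx, fd$test_idx)
    fit <- fit_booster(family, params_row, imp$train, y[train_idx],
                       seed = derive_seed(seed, k))
    preds[fd$test_idx] <<- predict(fit, xgboost::xgb.DMatrix(imp$test))
    tibble::tibble(
      fold_id = k,
      test_subject = fd$test_subject,
      n_test = length(fd$test_idx),
      train_subjects = list(unique(subj[train_idx])),
      test_subjects = list(unique(subj[fd$test_idx])),
      dropped_subject = list(dropped),
      impute_fit = "train"
    )
  })
  list(pred = preds, label = y, provenance = provenance)
}

#' Grid search over boosting hyperparameters by pooled LOSO AUC
#'
#' For each grid point the model is trained on every leave-one-subject-out
#' fold, the held-out predicted probabilities are pooled over folds, and
#' one AUC is computed; the grid point with the maximal pooled AUC wins
#' (ties go to the first point in grid order).
#'
#' @param family `"gbdt"` or `"xgboost"`.
#' @param grid Hyperparameter tibble (`n_learners`, `learning_rate`,
#'   `max_depth`); default [default_grid()].
#' @param features A `wear_features` matrix.
#' @param folds Folds from [loso_folds()].
#' @param seed Integer seed.
#' @param columns Feature columns to use (default: the matrix's block).
#' @return List `best` (one-row tibble with `auc`), `results` (all grid
#'   points with their pooled AUC).
#' @export
grid_search <- function(family = c("gbdt", "xgboost"), grid = default_grid(),
                        features, folds, seed = 1, columns = NULL) {
  family <- match.arg(family)
  if (!nrow(grid)) abort("empty grid")
  aucs <- vapply(seq_len(nrow(grid)), function(i) {
    res <- loso_predictions(family, grid[i, ], features, folds,
                            seed = derive_seed(seed, i), columns = columns)
    if (length(unique(res$label)) < 2) abort("pooled labels are degenerate")
    auc_rank(res$pred, res$label)
  }, double(1))
  results <- dplyr::mutate(grid, auc = aucs)
  list(best = results[which.max(aucs), ], results = results)
}

#' Evaluate a boosted classifier with subject-based leave-one-out
#'
#' Pools the held-out predictions of every LOSO fold and computes
#' accuracy, precision, recall, F1 and AUC (all in percent) at the given
#' probability threshold with MCI as the positive class, plus the ROC
#' point list and the final-model feature importances rescaled so the
#' most important feature is 100.
#'
#' @inheritParams grid_search
#' @param best_params One-row tibble (e.g. `grid_search(...)$best`).
#' @param threshold Classification threshold on the predicted
#'   probability.
#' @return Object of class `wear_eval`: metrics, `roc` tibble,
#'   `importance` tibble, pooled `predictions`, per-fold `provenance`.
#' @export
evaluate_model <- function(family = c("gbdt", "xgboost"), best_params,
                           features, folds, threshold = 0.5, seed = 1,
                           columns = NULL) {
  family <- match.arg(family)
  cols <- columns %||% feature_cols_of(features)
  res <- loso_predictions(family, best_params, features, folds, seed = seed,
                          columns = cols)
  y <- res$label
  p <- res$pred
  yhat <- as.integer(p >= threshold)
  tp <- sum(yhat == 1 & y == 1); fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1); tn <- sum(yhat == 0 & y == 0)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(precision) && is.finite(recall) &&
            precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  metrics <- tibble::tibble(
    accuracy = 100 * (tp + tn) / length(y),
    precision = precision, recall = recall, f1 = f1,
    auc = 100 * auc_rank(p, y)
  )
  # ROC points over the pooled scores
  ths <- c(Inf, sort(unique(p), decreasing = TRUE))
  roc <- purrr::map_dfr(ths, function(th) {
    tibble::tibble(threshold = th,
                   fpr = mean(p[y == 0] >= th),
                   tpr = mean(p[y == 1] >= th))
  })
  # importances from a final refit on all records
  Ximp <- impute_train_medians(as.data.frame(features[, cols, drop = FALSE]),
                               seq_along(y), seq_along(y))
  final <- fit_booster(family, best_params, Ximp$train, y,
                       seed = derive_seed(seed, 999))
  gain <- xgboost::xgb.importance(model = final)
  imp <- tibble::tibble(feature = cols, gain = 0)
  if (!is.null(gain) && nrow(gain)) {
    m <- match(gain$Feature, imp$feature)
    imp$gain[m[!is.na(m)]] <- gain$Gain[!is.na(m)]
  }
  imp$importance <- if (max(imp$gain) > 0) 100 * imp$gain / max(imp$gain) else 0
  structure(list(family = family, params = best_params,
                 threshold = threshold, metrics = metrics, roc = roc,
                 importance = dplyr::arrange(imp, dplyr::desc(.data$importance)),
                 predictions = tibble::tibble(
                   record_id = features$record_id,
                   subject_id = features$subject_id,
                   label = y, prob = p, predicted = yhat),
                 provenance = res$provenance,
                 mode = attr(features, "mode")),
            class = "wear_eval")
}

#' @export
print.wear_eval <- function(x, ...) {
  cat(sprintf("<wear_eval> %s (mode %s): ", x$family, x$mode %||% "?"))
  m <- x$metrics
  cat(sprintf("accuracy %.2f, precision %.2f, recall %.2f, F1 %.2f, AUC %.2f\n",
              m$accuracy, m$precision, m$recall, m$f1, m$auc))
  invisible(x)
}
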