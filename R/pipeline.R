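# End-to-end pipeline: cohort -> features -> selection -> grid search ->
# subject-based leave-one-out evaluation.

#' Run the full classification pipeline on a synthetic cohort
#'
#' Generates a seeded cohort, extracts the nocturnal feature matrix one
#' record at a time, runs per-group random-forest permutation-importance
#' selection (once on the full matrix, mirroring the selection-then-LOSO
#' sequence), grid-searches the boosting hyperparameters by pooled LOSO
#' AUC and evaluates the best model. The label-permuted control refits
#' everything with subject labels shuffled; its AUC is reported as the
#' mean over `n_permutations` independent shuffles to damp Monte-Carlo
#' noise in the no-signal check.
#'
#' @param n_per_arm Subjects per arm.
#' @param days_per_subject Nights per subject.
#' @param seed Integer seed controlling generation, selection, model
#'   fitting and the permuted control.
#' @param families Boosting families to evaluate.
#' @param grid Hyperparameter grid (a reduced grid keeps desk-scale runs
#'   fast; see [default_grid()] for the full surface).
#' @param mode Feature mode (`"P"`, `"P+S"`, `"S"`).
#' @param run_selection Run permutation-importance selection and restrict
#'   the models to the retained features?
#' @param permuted_control Also evaluate the label-permuted no-signal
#'   control?
#' @param n_permutations Shuffles averaged in the permuted control.
#' @return List: `features`, `selection`, and per family a list with
#'   `grid`, `eval` (a `wear_eval`) and `permuted_auc`.
#' @export
run_pipeline <- function(n_per_arm = 20, days_per_subject = 2, seed = 1,
                         families = c("gbdt", "xgboost"),
                         grid = tidyr::expand_grid(n_learners = c(50, 150),
                                                   learning_rate = 0.1,
                                                   max_depth = 3),
                         mode = "P", run_selection = TRUE,
                         permuted_control = TRUE, n_permutations = 3) {
  cohort <- generate_cohort(n_per_arm, n_per_arm,
                            days_per_subject = days_per_subject,
                            seed = seed, streams = character())
  feats_raw <- cohort_features(cohort$profiles,
                               days_per_subject = days_per_subject)
  features <- assemble_features(feats_raw, cohort$profiles, mode = mode)

  selection <- NULL
  cols <- feature_cols_of(features)
  if (run_selection && mode != "S") {
    imp <- purrr::map_dfr(unique(feature_groups()$group), function(g) {
      permutation_importance_by_group(features, group = g,
                                      seed = derive_seed(seed, 11))
    })
    selection <- select_features(imp)
    if (nrow(selection$retained)) cols <- selection$retained$feature
  }

  folds <- loso_folds(features$subject_id)
  out <- list(features = features, selection = selection)
  for (fam in families) {
    gs <- grid_search(fam, grid, features, folds,
                      seed = derive_seed(seed, 21), columns = cols)
    ev <- evaluate_model(fam, gs$best, features, folds,
                         seed = derive_seed(seed, 22), columns = cols)
    perm_auc <- NA_real_
    if (permuted_control) {
      perm_auc <- mean(vapply(seq_len(n_permutations), function(r) {
        permuted_auc(fam, gs$best, features, seed = derive_seed(seed, 30, r),
                     columns = cols)
      }, double(1)))
    }
    out[[fam]] <- list(grid = gs, eval = ev, permuted_auc = perm_auc)
  }
  out
}

# Pooled LOSO AUC after permuting labels at the record level (the
# no-signal control). Record-level permutation breaks the subject-label
# tie; permuting at the subject level instead leaves the held-out
# subject's label locally under-represented in every training fold, and
# that leave-one-out exclusion bias pushes the pooled null AUC well below
# 0.5 even with prior-stabilised folds.
permuted_auc <- function(family, params_row, features, seed, columns = NULL) {
  perm <- features
  with_seed(seed, {
    perm$label <- sample(perm$label)
  })
  folds <- loso_folds(perm$subject_id)
  res <- loso_predictions(family, params_row, perm, folds,
                          seed = derive_seed(seed, 1), columns = columns)
  auc_rank(res$pred, res$label)
}
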