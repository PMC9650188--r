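# broom-style tidiers for fitted/evaluated objects.

#' Tidy an evaluation report
#'
#' @param x A `wear_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return Long tibble `metric`, `value` (percent).
#' @export
tidy.wear_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.wear_eval
#' @return One-row tibble with family, mode, hyperparameters and metrics.
#' @export
glance.wear_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(family = x$family, mode = x$mode %||% NA_character_),
    x$params[, c("n_learners", "learning_rate", "max_depth")],
    x$metrics
  )
}

#' Tidy a feature-selection result
#'
#' @param x A `wear_selection` from [select_features()].
#' @param ... Unused.
#' @return Importance tibble with `candidate` and `retained` flags.
#' @export
tidy.wear_selection <- function(x, ...) {
  dplyr::mutate(
    x$importances,
    candidate = .data$feature %in% x$candidates$feature,
    retained = .data$feature %in% x$retained$feature
  )
}
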