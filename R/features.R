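# Record-level feature matrix: 7 rhythmic-signal groups x 36 sliding-window
# medians + a 28-column oxygen-desaturation group = 280 physiological
# features, optionally joined with 5 subjective scale features.

signal_groups <- c("hr", "rr", "spo2", "rmssd", "lf", "hf", "lf_hf")
scale_features <- c("education_years", "psqi_total", "sleep_disturbance",
                    "daytime_dysfunction", "chronic_disease_count")

window_starts_min <- function() seq(0, 350, by = 10)

#' Sliding-window medians over the night
#'
#' Windows of 20 min sliding by 10 min over 00:00-06:00: starts at 00:00,
#' 00:10, ..., 05:50 give exactly 36 windows, each `[start, start + 20) `
#' intersected with the night (the final window is truncated to 10 min).
#' The value of a window is the median of its available samples; an
#' all-missing window is `NA`.
#'
#' @param series Tibble with `window_start` (s) and a value column, e.g.
#'   one indicator from [window_indicators()].
#' @param value Name of the value column.
#' @param window,stride Window length and stride in seconds.
#' @param span Night span in seconds.
#' @return Named numeric vector of length 36.
#' @export
sliding_medians <- function(series, value = "value", window = 1200,
                            stride = 600, span = rw_constants$night_seconds) {
  starts <- seq(0, span - stride, by = stride)
  v <- series[[value]]
  tt <- series$window_start
  out <- vapply(starts, function(s) {
    sel <- tt >= s & tt < min(s + window, span)
    x <- v[sel]
    if (!length(x) || all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  }, double(1))
  names(out) <- sprintf("m%03d", starts / 60)
  out
}

#' Oxygen-desaturation feature group
#'
#' For each of the four oxygen indicators (ODI, mean OD duration,
#' percent SpO2 >= 95, percent SpO2 90-95): the six hourly values plus the
#' whole-night mean, 4 x 7 = 28 features. Missing hours propagate.
#'
#' @param hourly Output of [hourly_oxygen()] (6 rows).
#' @return Named numeric vector of length 28.
#' @export
od_feature_group <- function(hourly) {
  stopifnot(nrow(hourly) == 6)
  inds <- c("odi", "od_duration", "spo2_ge95", "spo2_90_95")
  out <- unlist(lapply(inds, function(ind) {
    v <- hourly[[ind]]
    setNames(c(v, mean(v)),
             c(sprintf("%s_h%d", ind, 0:5), paste0(ind, "_night")))
  }))
  out
}

#' Full physiological feature-column schema
#'
#' Deterministic, order-stable column names of the 280-column
#' physiological block: 36 window tags for each of the seven rhythmic
#' signals, then the 28 oxygen features.
#'
#' @return Character vector of length 280.
#' @export
feature_schema <- function() {
  wins <- sprintf("m%03d", window_starts_min())
  c(unlist(lapply(signal_groups, function(g) paste0(g, "_", wins))),
    names(od_feature_group(tibble::tibble(
      hour = 0:5, odi = 0, od_duration = 0, spo2_ge95 = 0,
      spo2_90_95 = 0, spo2_lt90 = 0))))
}

#' Map feature columns to their groups
#' @return Tibble `feature`, `group` covering the 280-column schema.
#' @export
feature_groups <- function() {
  sch <- feature_schema()
  tibble::tibble(
    feature = sch,
    group = c(rep(signal_groups, each = 36), rep("od", 28))
  )
}

#' Extract the 280 physiological features of one record
#'
#' Runs the nocturnal pipeline on one screened record: cardiac band-pass
#' of the first PPG channel (or EEMD denoising when `denoise = "eemd"`),
#' pulse-peak detection, per-30-s indicator windows, desaturation
#' analytics, then the sliding-window medians and the oxygen group.
#'
#' @param segments A `clean_segments` (or `raw_recording`, screened
#'   first).
#' @param denoise `"bandpass"` (zero-phase cardiac-band Butterworth) or
#'   `"eemd"` (ensemble empirical mode decomposition; considerably
#'   slower).
#' @param eemd_ensembles,eemd_seed EEMD settings when `denoise = "eemd"`.
#' @return One-row tibble with `subject_id`, `day_index` and the 280
#'   feature columns (NA-filled when the night streams were rejected).
#' @export
record_features <- function(segments, denoise = c("bandpass", "eemd"),
                            eemd_ensembles = 100, eemd_seed = 1) {
  denoise <- match.arg(denoise)
  segments <- screen_record(segments)
  sch <- feature_schema()
  base <- tibble::tibble(subject_id = segments$subject_id,
                         day_index = segments$day_index)
  feats <- setNames(rep(NA_real_, length(sch)), sch)
  if (!is.null(segments$ppg)) {
    fs <- rw_constants$ppg_rate
    cardiac <- if (denoise == "eemd") {
      eemd_denoise(segments$ppg$ch1, rate = fs,
                   n_ensembles = eemd_ensembles,
                   bands = list(rw_constants$cardiac_band), seed = eemd_seed)
    } else {
      bandpass_filter(segments$ppg$ch1, fs, rw_constants$cardiac_band)
    }
    pulse <- detect_peaks(cardiac, rate = fs)
    ind <- window_indicators(pulse, ppg = segments$ppg, spo2 = segments$spo2)
    for (g in signal_groups) {
      feats[paste0(g, "_", sprintf("m%03d", window_starts_min()))] <-
        sliding_medians(ind, value = g)
    }
  }
  if (!is.null(segments$spo2)) {
    ev <- detect_desaturations(segments$spo2)
    feats[names(od_feature_group(hourly_oxygen(segments$spo2, ev)))] <-
      od_feature_group(hourly_oxygen(segments$spo2, ev))
  }
  dplyr::bind_cols(base, tibble::as_tibble(as.list(feats)))
}

#' Extract features for a whole cohort, one record at a time
#'
#' Generates each subject-day's night streams from the profiles, extracts
#' its 280 features and discards the raw streams before moving on, so a
#' cohort never holds more than one night of raw signal in memory.
#'
#' @param profiles A cohort `profiles` tibble (see [generate_cohort()]).
#' @param days_per_subject Days per subject to generate.
#' @param streams Streams to generate per record.
#' @param progress Print a dot per record?
#' @return Tibble: `subject_id`, `day_index`, `label`, 280 feature
#'   columns.
#' @export
cohort_features <- function(profiles, days_per_subject = NULL,
                            streams = c("ppg", "spo2"), progress = FALSE) {
  rows <- purrr::pmap_dfr(
    tidyr::expand_grid(i = seq_len(nrow(profiles)),
                       day = seq_len(days_per_subject %||% profiles$n_days[1])),
    function(i, day) {
      rec <- generate_recording(profiles[i, ], day, streams = streams)
      out <- record_features(rec)
      if (progress) cat(".")
      out
    }
  )
  if (progress) cat("\n")
  dplyr::left_join(rows,
                   dplyr::select(profiles, "subject_id", label = "group"),
                   by = "subject_id") |>
    dplyr::relocate("label", .after = "day_index")
}

#' Assemble the modelling feature matrix
#'
#' Builds the record-level matrix in one of three modes: `"P"` (the 280
#' physiological columns per record), `"P+S"` (physiological plus the five
#' subjective scale features joined by subject), or `"S"` (the five scale
#' features only, with exactly one row per subject).
#'
#' @param records Tibble of record-level features (from
#'   [cohort_features()] or [record_features()] plus labels), with
#'   `subject_id` and `label` columns. Ignored in mode `"S"` except for
#'   validation.
#' @param scale_table Tibble with `subject_id`, `label` and the five scale
#'   columns (a cohort `profiles` tibble works).
#' @param mode `"P"`, `"P+S"` or `"S"`.
#' @return A `wear_features` tibble: `record_id`, `subject_id`, `label`,
#'   then the feature columns; attribute `"mode"` and
#'   `"feature_cols"` describe the block.
#' @export
assemble_features <- function(records, scale_table, mode = c("P", "P+S", "S")) {
  mode <- match.arg(mode)
  if ("group" %in% names(scale_table) && !"label" %in% names(scale_table)) {
    scale_table <- dplyr::rename(scale_table, label = "group")
  }
  sch <- feature_schema()
  if (mode == "S") {
    if (anyDuplicated(scale_table$subject_id)) {
      abort("duplicate subject rows in scale table (S mode uses one row per subject)")
    }
    out <- scale_table |>
      dplyr::transmute(record_id = .data$subject_id,
                       subject_id = .data$subject_id,
                       label = .data$label,
                       !!!rlang::syms(scale_features))
    return(new_wear_features(out, mode, scale_features))
  }
  unknown <- setdiff(records$subject_id, scale_table$subject_id)
  if (length(unknown)) {
    abort(sprintf("records reference unknown subjects: %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- records |>
    dplyr::mutate(record_id = paste0(.data$subject_id, "_d", .data$day_index)) |>
    dplyr::select("record_id", "subject_id", "label",
                  dplyr::all_of(sch))
  cols <- sch
  if (mode == "P+S") {
    out <- dplyr::left_join(
      out, dplyr::select(scale_table, "subject_id",
                         dplyr::all_of(scale_features)),
      by = "subject_id")
    cols <- c(sch, scale_features)
  }
  new_wear_features(out, mode, cols)
}

new_wear_features <- function(tbl, mode, feature_cols) {
  structure(tbl, mode = mode, feature_cols = feature_cols,
            class = c("wear_features", class(tbl)))
}

#' @export
print.wear_features <- function(x, ...) {
  cat(sprintf("<wear_features> mode %s: %d records, %d feature columns\n",
              attr(x, "mode"), nrow(x), length(attr(x, "feature_cols"))))
  NextMethod()
}
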