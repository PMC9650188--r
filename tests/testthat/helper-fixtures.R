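# Shared fixtures, all generated in code.

# A short pulse-like PPG trace with known beat times (constant spacing).
make_pulse_train <- function(spacing_s = 0.8, duration_s = 60, rate = 100) {
  tt <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  beats <- seq(spacing_s, duration_s - spacing_s, by = spacing_s)
  ext <- c(beats[1] - spacing_s, beats, beats[length(beats)] + spacing_s)
  phase <- approx(ext, seq_along(ext) - 1, xout = tt, rule = 2)$y
  list(time = tt, x = exp(3 * (cos(2 * pi * phase) - 1)), beats = beats)
}

# SpO2 trace at 1 Hz with trapezoid dips at known positions.
make_spo2_trapezoid <- function(baseline = 97, dips = list(),
                                duration_s = 3600) {
  tt <- seq(0, duration_s - 1)
  x <- rep(baseline, duration_s)
  for (d in dips) {  # d: list(start, depth, fall = 10, hold = 60, rec = 10)
    fall <- d$fall %||% 10; hold <- d$hold %||% 60; rec <- d$rec %||% 10
    seg <- tt - d$start
    dip <- ifelse(seg < 0, 0,
           ifelse(seg < fall, d$depth * seg / fall,
           ifelse(seg < fall + hold, d$depth,
           ifelse(seg < fall + hold + rec,
                  d$depth * (1 - (seg - fall - hold) / rec), 0))))
    x <- x - dip
  }
  tibble::tibble(time = tt, spo2 = x)
}

# Minimal raw recording wrapping provided streams.
make_recording <- function(accel = NULL, ppg = NULL, spo2 = NULL,
                           subject_id = "S001", day_index = 1) {
  structure(list(subject_id = subject_id, day_index = day_index,
                 accel = accel, ppg = ppg, spo2 = spo2,
                 diary = list(bed_time = 22.5, wake_time = 6.8),
                 artifacts = tibble::tibble(stream = character(),
                                            type = character(),
                                            start_s = double(),
                                            duration_s = double())),
            class = "raw_recording")
}

# A synthetic indicator series on the 30-s night grid.
make_indicator_series <- function(values) {
  tibble::tibble(window_start = seq(0, by = 30,
                                    length.out = length(values)),
                 value = values)
}

# Small record-level feature tibble with constant-filled physiological
# columns, for schema/assembly tests.
make_feature_records <- function(subjects, days = 1, fill = 0) {
  sch <- rhythmwear::feature_schema()
  tidyr::expand_grid(subject_id = subjects, day_index = seq_len(days)) |>
    dplyr::bind_cols(tibble::as_tibble(
      as.list(setNames(rep(fill, length(sch)), sch))))
}

make_scale_table <- function(subjects, labels) {
  tibble::tibble(subject_id = subjects, label = labels,
                 education_years = 10, psqi_total = 6,
                 sleep_disturbance = 1, daytime_dysfunction = 1,
                 chronic_disease_count = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
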