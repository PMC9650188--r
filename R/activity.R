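# Daytime physical-activity features: activity counts, per-minute PA,
# non-wear detection, percentile activity states, rhythm-curve compression
# and per-period summaries.

#' Convert a filtered vertical acceleration channel to per-second counts
#'
#' The (band-passed, gravity-removed) vertical channel is resampled to
#' 30 Hz and rectified; in each 1-s block of 30 samples the amplitude in
#' excess of the dead-band, clipped at the ceiling, is summed and divided
#' by the count resolution:
#' `count = round( sum( min(max(|a| - deadband, 0), ceiling) ) / resolution )`.
#'
#' @param x Numeric acceleration channel (g), already band-pass filtered.
#' @param rate Input sampling rate, Hz.
#' @param deadband,ceiling,resolution Count-mapping constants in g (the
#'   resolution is in g*sample per count unit).
#' @return Integer vector, one count value per whole second of input.
#' @export
#' @examples
#' accel_to_counts(rep(0.15, 50), rate = 25)  # 300 per second
accel_to_counts <- function(x, rate = rw_constants$accel_rate,
                            deadband = rw_constants$count_deadband_g,
                            ceiling = rw_constants$count_ceiling_g,
                            resolution = rw_constants$count_resolution) {
  if (!length(x)) return(integer())
  fs <- rw_constants$count_rate
  dur <- length(x) / rate
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  xr <- approx(seq(0, dur - 1 / rate, by = 1 / rate), x, xout = tt,
               rule = 2)$y
  n_sec <- length(xr) %/% fs
  if (!n_sec) return(integer())
  xr <- xr[seq_len(n_sec * fs)]
  excess <- pmin(pmax(abs(xr) - deadband, 0), ceiling)
  as.integer(round(colSums(matrix(excess, nrow = fs)) / resolution))
}

#' Per-minute physical activity (PA)
#'
#' PA for a minute is the sum of its 60 per-second count values. A partial
#' trailing minute is dropped (recorded in attribute `"dropped_seconds"`).
#'
#' @param counts Integer per-second counts.
#' @param start_minute Clock minute of the first count (minutes since
#'   08:00 by convention).
#' @return Tibble with `minute` and `pa`.
#' @export
pa_series <- function(counts, start_minute = 0) {
  n_min <- length(counts) %/% 60
  dropped <- length(counts) - n_min * 60
  pa <- if (n_min) {
    colSums(matrix(counts[seq_len(n_min * 60)], nrow = 60))
  } else {
    double()
  }
  out <- tibble::tibble(minute = start_minute + seq_len(n_min) - 1,
                        pa = as.integer(pa))
  if (dropped) attr(out, "dropped_seconds") <- dropped
  out
}

#' Detect non-wear minutes
#'
#' A maximal run of consecutive zero-PA minutes strictly longer than 90
#' minutes is flagged as non-wear; every other minute is wear time. The
#' rule is idempotent and invariant to shifting the clock.
#'
#' @param pa Tibble with a `pa` column (e.g. from [pa_series()]).
#' @param threshold_minutes Run length above which (strictly) a zero run
#'   is non-wear.
#' @return The input with a logical `wear` column added (replaced if
#'   present).
#' @export
detect_nonwear <- function(pa, threshold_minutes = rw_constants$nonwear_minutes) {
  z <- pa$pa == 0
  r <- rle(z)
  nonwear <- rep(r$values & r$lengths > threshold_minutes, r$lengths)
  dplyr::mutate(pa, wear = !nonwear)
}

#' Percentile activity-state thresholds
#'
#' The 40th/70th/90th percentiles (linear-interpolation convention) of the
#' pooled wear-minute PA distribution of the current analysis set. One
#' shared threshold triple is used per run so that states are comparable
#' across subjects.
#'
#' @param pa_pool Numeric vector of wear-minute PA values, pooled over all
#'   records in the analysis set.
#' @return Named list `p40`, `p70`, `p90`.
#' @export
#' @examples
#' state_thresholds(1:10)  # p40 = 4.6, p70 = 7.3, p90 = 9.1
state_thresholds <- function(pa_pool) {
  pa_pool <- pa_pool[!is.na(pa_pool)]
  if (!length(pa_pool)) abort("empty PA pool")
  q <- quantile(pa_pool, c(0.4, 0.7, 0.9), type = 7, names = FALSE)
  list(p40 = q[1], p70 = q[2], p90 = q[3])
}

#' Classify wear minutes into activity states
#'
#' Assigns `sedentary` (PA < p40), `low` (p40 <= PA < p70), `median`
#' (p70 <= PA < p90) or `high` (PA >= p90) to every wear minute; ties go
#' upward at p90, so a degenerate pool where every PA is equal classifies
#' every wear minute as `high`. Non-wear minutes get `NA`.
#'
#' @param pa Tibble with `pa` and `wear` columns.
#' @param thresholds Output of [state_thresholds()].
#' @return The input with a `state` factor column added.
#' @export
classify_states <- function(pa, thresholds) {
  lv <- c("sedentary", "low", "median", "high")
  st <- with(thresholds, dplyr::case_when(
    pa$pa >= p90 ~ "high",
    pa$pa >= p70 ~ "median",
    pa$pa >= p40 ~ "low",
    TRUE ~ "sedentary"
  ))
  st[!pa$wear] <- NA
  dplyr::mutate(pa, state = factor(st, levels = lv))
}

#' Block-median curve compression
#'
#' Reduces consecutive non-overlapping blocks of `block` points to their
#' median; a trailing partial block is reduced to its own median. A
#' 720-point series with block 5 compresses to 144 points.
#'
#' @param x Numeric series.
#' @param block Block length in points.
#' @return Numeric vector of block medians.
#' @export
compress_curve <- function(x, block = 5) {
  stopifnot(block >= 1)
  if (!length(x)) return(double())
  g <- ceiling(seq_along(x) / block)
  as.numeric(tapply(x, g, median, na.rm = TRUE))
}

#' Table of daytime summary periods (hours since midnight)
#' @return Tibble `period`, `start_h`, `end_h`.
#' @export
day_periods <- function() {
  tibble::tibble(
    period = c("08:00-09:00", "09:00-11:00", "11:00-13:00", "13:00-15:00",
               "15:00-17:00", "17:00-19:00", "19:00-20:00"),
    start_h = c(8, 9, 11, 13, 15, 17, 19),
    end_h = c(9, 11, 13, 15, 17, 19, 20)
  )
}

#' Table of nocturnal summary periods (hours since midnight)
#' @return Tibble `period`, `start_h`, `end_h`.
#' @export
night_periods <- function() {
  tibble::tibble(
    period = c("00:00-01:00", "01:00-03:00", "03:00-05:00", "05:00-06:00"),
    start_h = c(0, 1, 3, 5),
    end_h = c(1, 3, 5, 6)
  )
}

#' Per-period means of a rhythm curve
#'
#' Averages a (typically compressed) rhythm curve over clock-time periods.
#' With `normalize = TRUE` the curve is min-max scaled to `[0, 1]` per
#' record before averaging, matching the normalised daytime summaries.
#'
#' @param curve Tibble with `hour` (hours since midnight) and `value`.
#' @param periods Period table, e.g. [day_periods()] or [night_periods()].
#' @param normalize Min-max scale the curve before averaging?
#' @return Tibble `period`, `mean` (NA where a period has no data).
#' @export
period_summary <- function(curve, periods = day_periods(), normalize = FALSE) {
  v <- curve$value
  if (normalize) {
    rng <- range(v, na.rm = TRUE)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  }
  purrr::pmap_dfr(periods, function(period, start_h, end_h) {
    sel <- curve$hour >= start_h & curve$hour < end_h
    m <- if (any(sel)) mean(v[sel], na.rm = TRUE) else NA_real_
    tibble::tibble(period = period, mean = m)
  })
}

#' Daytime activity pipeline for one record
#'
#' Band-passes the vertical channel, converts it to counts and per-minute
#' PA, flags non-wear and returns the minute-level activity table.
#'
#' @param segments A `clean_segments` (or `raw_recording`, screened first).
#' @return Tibble `minute`, `pa`, `wear`, or `NULL` when the acceleration
#'   stream was rejected.
#' @export
minute_activity <- function(segments) {
  segments <- screen_record(segments)
  if (is.null(segments$accel)) return(NULL)
  filt <- bandpass_accel(segments$accel$z, rate = rw_constants$accel_rate)
  counts <- accel_to_counts(as.numeric(filt))
  detect_nonwear(pa_series(counts))
}
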