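# Record screening and signal conditioning.

# Zero-phase IIR filtering: odd-reflection padding plus steady-state
# initial conditions for the padded edge value, forward-backward, trim.
# Removes the edge transients a plain forward-backward pass leaves behind.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1, 250)
  ext <- c(2 * x[1] - x[seq(padlen + 1, 2)], x,
           2 * x[n] - x[seq(n - 1, n - padlen)])
  dc <- sum(b) / sum(a)
  pass <- function(v) {
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(v[1], length(b) - 1),
                              init.y = rep(v[1] * dc, length(a) - 1)))
  }
  y <- pass(ext)
  y <- rev(pass(rev(y)))
  y[seq(padlen + 1, padlen + n)]
}

#' Screen a raw recording and crop it to the analysis windows
#'
#' Applies the data-cleansing rules stream by stream: a stream is rejected
#' when (a) more than half of its samples are identically zero or missing
#' (`null_signal`), (b) its variability falls below the flatline threshold
#' (`flat_signal`), or (c) it does not fully cover its analysis window
#' (`truncated` if it partially overlaps, `outside_window` if not at all).
#' Accepted streams are cropped to the fixed windows: acceleration to
#' 08:00-20:00 and PPG/SpO2 to 00:00-06:00. Screening never raises on bad
#' data; it returns reasons. Screening an already screened record returns
#' it unchanged (idempotence).
#'
#' @param recording A `raw_recording` (or an already screened
#'   `clean_segments`, returned as is).
#' @return A `clean_segments` object: list with the cropped `accel`, `ppg`,
#'   `spo2` streams (rejected streams are `NULL`), the `diary`, and a
#'   `rejection` tibble (`stream`, `reason`) with one reason per rejected
#'   stream.
#' @export
screen_record <- function(recording) {
  if (inherits(recording, "clean_segments")) return(recording)
  stopifnot(inherits(recording, "raw_recording"))
  flat <- rw_constants$flatline_frac
  spans <- list(accel = rw_constants$day_seconds,
                ppg = rw_constants$night_seconds,
                spo2 = rw_constants$night_seconds)
  full_scale <- list(accel = 2, ppg = 2, spo2 = 100)

  out <- list(subject_id = recording$subject_id,
              day_index = recording$day_index,
              diary = recording$diary,
              accel = NULL, ppg = NULL, spo2 = NULL)
  rej <- tibble::tibble(stream = character(), reason = character())

  for (st in c("accel", "ppg", "spo2")) {
    dat <- recording[[st]]
    if (is.null(dat)) next
    vals <- as.matrix(dat[setdiff(names(dat), "time")])
    null_frac <- mean(rowSums(vals == 0 | is.na(vals)) == ncol(vals))
    span <- spans[[st]]
    covered <- nrow(dat) > 0 &&
      min(dat$time) <= 1 && max(dat$time) >= span - 2
    overlap <- nrow(dat) > 0 && max(dat$time) > 0 && min(dat$time) < span
    reason <- if (null_frac > 0.5) {
      "null_signal"
    } else if (max(apply(vals, 2, stats::sd), na.rm = TRUE) <
               flat * full_scale[[st]]) {
      "flat_signal"
    } else if (!covered) {
      if (overlap) "truncated" else "outside_window"
    } else {
      NA_character_
    }
    if (is.na(reason)) {
      out[[st]] <- dplyr::filter(dat, .data$time >= 0, .data$time < span)
    } else {
      rej <- dplyr::bind_rows(rej, tibble::tibble(stream = st, reason = reason))
    }
  }
  out$rejection <- rej
  structure(out, class = "clean_segments")
}

#' Zero-phase Butterworth band-pass for acceleration channels
#'
#' Fourth-order Butterworth band-pass with corners at 0.2 Hz and
#' `min(15, 0.45 * rate)` Hz, applied forward-backward (zero phase) so the
#' filtered stream stays time-aligned with the other streams. At the
#' 25 Hz accelerometer rate the nominal 15 Hz upper corner would sit above
#' the 12.5 Hz Nyquist limit; it is clipped to `0.45 * rate` with a
#' warning recorded in the `"clipped_corner"` attribute.
#'
#' @param x Numeric acceleration channel.
#' @param rate Sampling rate in Hz.
#' @param band Nominal corner frequencies in Hz.
#' @param order Filter order (of the analogue prototype).
#' @return Filtered numeric vector, same length as the input.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1 / 25)
#' out <- bandpass_accel(sin(2 * pi * 1 * t), rate = 25)
bandpass_accel <- function(x, rate = rw_constants$accel_rate,
                           band = c(0.2, 15), order = 4) {
  ncoef <- 2 * order + 1
  if (length(x) < 3 * ncoef) {
    abort(sprintf(
      "input too short to pad a %d-coefficient filter (need >= %d samples)",
      ncoef, 3 * ncoef))
  }
  hi <- band[2]
  clipped <- FALSE
  if (hi >= rate / 2) {
    hi <- 0.45 * rate
    clipped <- TRUE
  }
  out <- bandpass_filter(x, rate, c(band[1], hi), order = order)
  if (clipped) {
    attr(out, "clipped_corner") <- hi
  }
  out
}

#' Zero-phase Butterworth band-pass
#'
#' General zero-phase (forward-backward) Butterworth band-pass used for
#' cardiac- and respiratory-band conditioning.
#'
#' @inheritParams bandpass_accel
#' @export
bandpass_filter <- function(x, rate, band, order = 4) {
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  zero_phase_filter(bf$b, bf$a, x)
}
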