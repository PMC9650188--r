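# Seeded synthetic cohort generator: subject profiles with planted
# MCI-vs-control contrasts, and per-subject-day raw sensor streams.

# Deterministic sub-seed derivation (Lehmer step per component, < 2^31).
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ks) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic study cohort
#'
#' Draws subject profiles for the two groups and (optionally) synthesises
#' the raw sensor streams for every subject-day: daytime tri-axial
#' acceleration at 25 Hz (08:00-20:00), nocturnal dual-channel PPG at
#' 100 Hz and a 1 Hz SpO2 series (00:00-06:00), plus a sleep-diary entry.
#' MCI profiles are drawn with a flattened nocturnal HRV peak, larger LF/HF
#' variability, more frequent and deeper desaturations, a lower
#' high-intensity activity fraction and a positive morning low-activity
#' bias relative to the control defaults (see [group_defaults()]).
#'
#' Raw streams are large (a single night of dual-channel PPG is 4.3 million
#' samples); for cohort-scale feature extraction prefer
#' [cohort_features()], which generates and discards one recording at a
#' time, or restrict `streams`.
#'
#' @param n_mci,n_control Number of subjects per arm (non-negative).
#' @param days_per_subject Recording days per subject (>= 1).
#' @param seed Integer seed; output is fully determined by the arguments.
#' @param streams Which raw streams to synthesise: any of `"accel"`,
#'   `"ppg"`, `"spo2"`. Profiles are always generated.
#' @param overrides Named list merged over the group defaults (applied to
#'   both groups), e.g. `list(pp_jitter_ms = 0)` for noise-free nights.
#' @return An object of class `wear_cohort`: a list with `profiles`
#'   (a tibble, one row per subject) and `recordings` (a list of
#'   `raw_recording` objects, empty when `streams` is empty).
#' @export
#' @examples
#' coh <- generate_cohort(2, 2, days_per_subject = 1, seed = 1,
#'                        streams = "spo2")
#' coh$profiles$group
generate_cohort <- function(n_mci, n_control, days_per_subject = 1, seed,
                            streams = c("accel", "ppg", "spo2"),
                            overrides = NULL) {
  if (n_mci < 0 || n_control < 0) {
    abort("`n_mci` and `n_control` must be non-negative counts.")
  }
  if (days_per_subject < 1) abort("`days_per_subject` must be >= 1.")
  if (missing(seed)) abort("`seed` is required.")
  streams <- if (length(streams)) {
    match.arg(streams, c("accel", "ppg", "spo2"), several.ok = TRUE)
  } else {
    character()
  }

  groups <- c(rep("MCI", n_mci), rep("control", n_control))
  profiles <- purrr::imap_dfr(groups, function(g, i) {
    draw_profile(g, i, days_per_subject, derive_seed(seed, i),
                 overrides = overrides)
  })

  recordings <- list()
  if (length(streams) && nrow(profiles)) {
    recordings <- purrr::pmap(
      tidyr::expand_grid(i = seq_len(nrow(profiles)),
                         day = seq_len(days_per_subject)),
      function(i, day) {
        generate_recording(profiles[i, ], day, streams = streams)
      }
    )
  }

  structure(list(profiles = profiles, recordings = recordings,
                 seed = seed),
            class = "wear_cohort")
}

# One subject profile: scale features + circadian parameters drawn around
# the group defaults.
draw_profile <- function(group, index, n_days, seed, overrides = NULL) {
  defs <- group_defaults(group)
  if (!is.null(overrides)) defs[names(overrides)] <- overrides
  with_seed(seed, {
    mci <- group == "MCI"
    scale <- tibble::tibble(
      education_years = round(clamp(rnorm(1, if (mci) 9 else 12, 3), 0, 20)),
      psqi_total = round(clamp(rnorm(1, if (mci) 7.2 else 5.4,
                                     if (mci) 4.4 else 2.8), 0, 21)),
      sleep_disturbance = round(clamp(rnorm(1, if (mci) 1.27 else 1.06,
                                            if (mci) 0.59 else 0.36), 0, 3)),
      daytime_dysfunction = round(clamp(rnorm(1, if (mci) 1.22 else 0.65,
                                              if (mci) 1.03 else 0.66), 0, 3)),
      chronic_disease_count = rpois(1, if (mci) 1.45 else 0.75)
    )
    jit <- function(p, nm) {
      s <- subject_sds[[nm]]
      if (is.null(s)) p else p + rnorm(1, 0, s)
    }
    circ <- defs
    for (nm in names(subject_sds)) circ[[nm]] <- jit(circ[[nm]], nm)
    circ$hrv_peak_amplitude <- max(circ$hrv_peak_amplitude, 0)
    circ$desat_rate_per_hour <- max(circ$desat_rate_per_hour, 0)
    circ$desat_depth_points <- max(circ$desat_depth_points, 4.5)
    circ$high_activity_fraction <- clamp(circ$high_activity_fraction, 0, 1)
    tibble::tibble(
      subject_id = sprintf("S%03d", index),
      group = group,
      n_days = n_days,
      seed = seed,
      !!!scale,
      params = list(circ)
    )
  })
}

#' Synthesise one subject-day of raw streams
#'
#' @param profile One row of a cohort `profiles` tibble.
#' @param day_index Day number (1-based).
#' @param streams Streams to generate (subset of accel/ppg/spo2).
#' @return A `raw_recording`: list with `subject_id`, `day_index`, `accel`
#'   (tibble time/x/y/z, seconds since 08:00), `ppg` (time/ch1/ch2, seconds
#'   since 00:00), `spo2` (time/spo2), `diary` (bed/wake, hours), and
#'   `artifacts` metadata. Planted desaturation events are attached as
#'   attribute `"planted_desats"` on the `spo2` tibble.
#' @export
generate_recording <- function(profile, day_index = 1,
                               streams = c("accel", "ppg", "spo2")) {
  stopifnot(nrow(profile) == 1)
  params <- profile$params[[1]]
  dseed <- derive_seed(profile$seed, 7, day_index)
  rec <- list(subject_id = profile$subject_id, day_index = day_index,
              accel = NULL, ppg = NULL, spo2 = NULL,
              artifacts = tibble::tibble(stream = character(),
                                         type = character(),
                                         start_s = double(),
                                         duration_s = double()))
  rec$diary <- with_seed(derive_seed(dseed, 1), {
    list(bed_time = runif(1, 21.5, 23.8), wake_time = runif(1, 6.1, 7.8))
  })
  if (any(c("ppg", "spo2") %in% streams)) {
    night <- synth_night_ppg(params, seed = derive_seed(dseed, 2))
    if ("ppg" %in% streams) rec$ppg <- night$ppg
    if ("spo2" %in% streams) rec$spo2 <- night$spo2
  }
  if ("accel" %in% streams) {
    rec$accel <- synth_day_accel(params, seed = derive_seed(dseed, 3))
  }
  structure(rec, class = "raw_recording")
}

#' Synthesise one night of dual-channel PPG and SpO2
#'
#' The cardiac component is a pulse train whose beat-to-beat intervals are
#' modulated by a low-frequency (~0.1 Hz) oscillation and a
#' respiratory-coupled high-frequency oscillation, with the modulation
#' depth following a smooth nocturnal curve peaking at the profile's HRV
#' peak hour. A respiratory oscillation at the profile's respiratory rate
#' is mixed into both channels with different gains. SpO2 is generated at
#' 1 Hz as a 97-99 percent baseline with trapezoid desaturation episodes
#' (linear fall, hold, linear recovery) arriving as a Poisson process.
#'
#' @param params Named list of circadian parameters (see [group_defaults()]);
#'   a one-row profile tibble is also accepted.
#' @param seed Integer seed.
#' @param night_seconds Night duration, default six hours.
#' @return List with `ppg` (tibble time/ch1/ch2 at 100 Hz) and `spo2`
#'   (tibble time/spo2 at 1 Hz, planted events in attribute
#'   `"planted_desats"`).
#' @export
synth_night_ppg <- function(params, seed, night_seconds = rw_constants$night_seconds) {
  if (inherits(params, "data.frame")) params <- params$params[[1]]
  fs <- rw_constants$ppg_rate
  with_seed(seed, {
    t0_ms <- 60000 / params$mean_hr_bpm
    f_resp <- params$resp_rate_bpm / 60
    f_lf <- 0.095
    n_beats <- ceiling(night_seconds / (t0_ms / 1000)) + 16
    tk <- (seq_len(n_beats) - 1) * t0_ms / 1000
    depth <- hrv_depth_curve(tk / 3600, params$hrv_peak_amplitude,
                             params$hrv_peak_hour)
    # slow log-normal wobble of the LF amplitude (spline through hourly draws)
    knots <- seq(0, night_seconds + 3600, by = 3600)
    wob <- spline(knots, rnorm(length(knots)), xout = tk)$y
    hf_amp <- params$hrv_hf_amp_ms
    lf_amp <- hf_amp * sqrt(params$lfhf_mean) * exp(params$lfhf_jitter * wob)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    pp <- t0_ms +
      depth * (hf_amp * sin(2 * pi * f_resp * tk + ph1) +
               lf_amp * sin(2 * pi * f_lf * tk + ph2)) +
      rnorm(n_beats, 0, params$pp_jitter_ms)
    pp <- clamp(pp, 350, 2500)
    beat_t <- runif(1, 0, t0_ms / 1000) + cumsum(pp) / 1000
    beat_t <- beat_t[beat_t < night_seconds + 2]

    tg <- seq(0, night_seconds - 1 / fs, by = 1 / fs)
    nb <- length(beat_t)
    ext <- c(2 * beat_t[1] - beat_t[2], beat_t, 2 * beat_t[nb] - beat_t[nb - 1])
    phase <- approx(ext, seq_along(ext) - 1, xout = tg, rule = 2)$y
    pulse <- exp(3 * (cos(2 * pi * phase) - 1))
    pulse <- pulse - mean(pulse)
    resp <- sin(2 * pi * f_resp * tg + runif(1, 0, 2 * pi))
    noise <- params$ppg_noise_sd
    ppg <- tibble::tibble(
      time = tg,
      ch1 = 1.00 * pulse + 0.45 * resp +
        (if (noise > 0) rnorm(length(tg), 0, noise) else 0),
      ch2 = 0.55 * pulse + 1.00 * resp +
        (if (noise > 0) rnorm(length(tg), 0, noise) else 0)
    )

    spo2 <- synth_spo2(params, night_seconds)
    list(ppg = ppg, spo2 = spo2)
  })
}

# SpO2 trace with trapezoid desaturation episodes; called inside the night
# seed context so it shares the night's RNG stream.
synth_spo2 <- function(params, night_seconds) {
  ts <- seq(0, night_seconds - 1)
  baseline <- runif(1, 97.2, 99)
  x <- rep(baseline, length(ts))
  rate <- params$desat_rate_per_hour
  events <- tibble::tibble(start = double(), depth = double(),
                           hold = double(), duration = double())
  if (rate > 0) {
    n_ev <- rpois(1, rate * night_seconds / 3600)
    if (n_ev > 0) {
      fall_s <- 15; rec_s <- 20
      starts <- sort(runif(n_ev, 0, night_seconds - 200))
      holds <- runif(n_ev, params$desat_hold_min_s, params$desat_hold_max_s)
      depths <- params$desat_depth_points + runif(n_ev, 0, 3)
      keep <- rep(TRUE, n_ev)
      last_end <- -Inf
      for (i in seq_len(n_ev)) {
        if (starts[i] < last_end + 130) { keep[i] <- FALSE; next }
        last_end <- starts[i] + fall_s + holds[i] + rec_s
      }
      starts <- starts[keep]; holds <- holds[keep]; depths <- depths[keep]
      for (i in seq_along(starts)) {
        s <- starts[i]; d <- depths[i]; h <- holds[i]
        seg <- ts - s
        dip <- ifelse(seg < 0, 0,
               ifelse(seg < fall_s, d * seg / fall_s,
               ifelse(seg < fall_s + h, d,
               ifelse(seg < fall_s + h + rec_s,
                      d * (1 - (seg - fall_s - h) / rec_s), 0))))
        x <- x - dip
      }
      events <- tibble::tibble(start = starts, depth = depths, hold = holds,
                               duration = fall_s + holds + rec_s)
    }
  }
  out <- tibble::tibble(time = ts, spo2 = clamp(x, 50, 100))
  attr(out, "planted_desats") <- events
  out
}

# Per-minute activity intensity draw shared by the acceleration
# synthesiser; consumes the caller's RNG stream.
draw_minute_intensity <- function(params, n_min) {
  hour <- 8 + (seq_len(n_min) - 1) / 60
  intensity <- activity_template(hour) * params$activity_scale *
    exp(rnorm(n_min, 0, 0.35))
  burst <- runif(n_min) < params$high_activity_fraction
  intensity[burst] <- intensity[burst] * 2.5
  bias <- params$morning_low_activity_bias
  if (bias > 0) {
    morning <- hour < 11
    intensity[morning] <- intensity[morning] * (1 - 0.6 * bias)
    zeroed <- morning & runif(n_min) < 0.3 * bias
    intensity[zeroed] <- intensity[zeroed] * 0.05
  }
  intensity
}

#' Per-minute activity-intensity draw for one subject-day
#'
#' The minute-level intensity envelope that [synth_day_accel()] turns into
#' an acceleration stream: diurnal template times subject scale, with
#' high-activity bursts and the morning low-activity bias applied. Useful
#' for cohort-scale Monte-Carlo checks of the planted activity contrasts
#' without synthesising full-rate acceleration.
#'
#' @inheritParams synth_night_ppg
#' @param n_min Minutes in the day window (default 720).
#' @return Numeric vector of minute intensities (g).
#' @export
synth_minute_intensity <- function(params, seed,
                                   n_min = rw_constants$day_seconds %/% 60) {
  if (inherits(params, "data.frame")) params <- params$params[[1]]
  with_seed(seed, draw_minute_intensity(params, n_min))
}

#' Synthesise one day of tri-axial acceleration
#'
#' Per-minute activity intensity follows a bimodal diurnal template
#' (morning peak around 08:40, post-lunch trough at 13:00-14:00, evening
#' rebound), scaled by the profile's activity parameters: a
#' `high_activity_fraction` of minutes receive burst intensity, and a
#' positive `morning_low_activity_bias` damps and zeroes out morning
#' minutes. Acceleration within each minute is a zero-mean oscillation at
#' gait frequency whose envelope is the minute intensity, plus 1 g gravity
#' on the vertical axis.
#'
#' @inheritParams synth_night_ppg
#' @param day_seconds Day duration, default twelve hours (08:00-20:00).
#' @return Tibble `time` (seconds since 08:00), `x`, `y`, `z` (g) at 25 Hz;
#'   the vertical axis is `z`. Per-minute intensities are attached as
#'   attribute `"minute_intensity"`.
#' @export
synth_day_accel <- function(params, seed, day_seconds = rw_constants$day_seconds) {
  if (inherits(params, "data.frame")) params <- params$params[[1]]
  fs <- rw_constants$accel_rate
  with_seed(seed, {
    n_min <- day_seconds %/% 60
    intensity <- draw_minute_intensity(params, n_min)
    spm <- 60 * fs
    tt <- seq(0, day_seconds - 1 / fs, by = 1 / fs)
    f_gait <- rep(runif(n_min, 1.6, 2.2), each = spm)
    ph <- rep(runif(n_min, 0, 2 * pi), each = spm)
    env <- rep(intensity, each = spm)
    osc <- env * sin(2 * pi * f_gait * tt + ph)
    out <- tibble::tibble(
      time = tt,
      x = 0.4 * env * sin(2 * pi * f_gait * tt + ph + 1.1),
      y = 0.3 * env * sin(2 * pi * f_gait * tt + ph + 2.3),
      z = 1 + osc
    )
    attr(out, "minute_intensity") <- intensity
    out
  })
}

#' Inject recording artifacts
#'
#' Emulates device failure modes on a copy of the recording: `null_gap`
#' (the stream records zeros), `flatline` (the stream holds its value at
#' the artifact start) and `clip` (samples saturate at the channel
#' maximum over the interval). Injected intervals are appended to the
#' recording's `artifacts` metadata so tests can assert on them.
#'
#' @param recording A `raw_recording`.
#' @param artifact_spec Tibble/data frame with columns `stream`
#'   (accel/ppg/spo2), `type` (null_gap/flatline/clip), `start_s`,
#'   `duration_s` (seconds, stream-local time).
#' @return A modified copy of `recording`.
#' @export
inject_artifacts <- function(recording, artifact_spec) {
  stopifnot(inherits(recording, "raw_recording"))
  spec <- tibble::as_tibble(artifact_spec)
  if (!nrow(spec)) return(recording)
  req <- c("stream", "type", "start_s", "duration_s")
  if (!all(req %in% names(spec))) {
    abort("`artifact_spec` needs columns stream, type, start_s, duration_s.")
  }
  for (i in seq_len(nrow(spec))) {
    st <- spec$stream[i]
    dat <- recording[[st]]
    if (is.null(dat)) abort(sprintf("stream '%s' not present in recording", st))
    lo <- spec$start_s[i]; hi <- lo + spec$duration_s[i]
    if (lo < min(dat$time) || hi > max(dat$time) + 1) {
      abort("artifact interval lies outside the recording span")
    }
    idx <- dat$time >= lo & dat$time < hi
    cols <- setdiff(names(dat), "time")
    for (cl in cols) {
      dat[[cl]] <- switch(spec$type[i],
        null_gap = replace(dat[[cl]], idx, 0),
        flatline = replace(dat[[cl]], idx, dat[[cl]][which(idx)[1]]),
        clip     = replace(dat[[cl]], idx, max(dat[[cl]], na.rm = TRUE)),
        abort(sprintf("unknown artifact type '%s'", spec$type[i]))
      )
    }
    recording[[st]] <- dat
  }
  recording$artifacts <- dplyr::bind_rows(recording$artifacts, spec[req])
  recording
}
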