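# Nocturnal physiology: pulse peaks, HRV indicators, respiratory rate,
# SpO2 desaturation analytics, per-30-s indicator windows.

#' Detect pulse peaks in a cardiac-band PPG channel
#'
#' Local-maximum detection with an adaptive amplitude threshold (the 60th
#' percentile of the signal over 60-s blocks, interpolated between block
#' centres) and a 300 ms refractory period. Peak positions are refined by
#' parabolic interpolation, and successive peak intervals are gated to the
#' physiologic (250, 3000) ms range; removals are counted in `n_gated`.
#'
#' @param x Cardiac-band PPG channel (denoised/band-passed).
#' @param rate Sampling rate, Hz.
#' @return List of class `pulse_series`: `peak_times` (s), `pp_intervals`
#'   (ms, gated), `n_gated`.
#' @export
detect_peaks <- function(x, rate = rw_constants$ppg_rate) {
  n <- length(x)
  empty <- structure(list(peak_times = double(), pp_intervals = double(),
                          n_gated = 0L), class = "pulse_series")
  if (n < 3) return(empty)
  # blockwise 60-s 60th-percentile threshold, linearly interpolated
  blk <- as.integer(60 * rate)
  g <- ceiling(seq_len(n) / blk)
  qs <- tapply(x, g, quantile, probs = 0.6, names = FALSE)
  centres <- (as.numeric(names(qs)) - 0.5) * blk
  thr <- if (length(qs) > 1) {
    approx(centres, qs, xout = seq_len(n), rule = 2)$y
  } else {
    rep(qs[[1]], n)
  }
  core <- 2:(n - 1)
  cand <- core[x[core] > x[core - 1] & x[core] >= x[core + 1] &
                 x[core] > thr[core]]
  if (!length(cand)) return(empty)
  # refractory: keep a candidate only if far enough from the last kept one
  refr <- rw_constants$refractory_s * rate
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] - last >= refr) {
      keep[i] <- TRUE
      last <- cand[i]
    }
  }
  pk <- cand[keep]
  # parabolic refinement to sub-sample peak times
  num <- x[pk - 1] - x[pk + 1]
  den <- x[pk - 1] - 2 * x[pk] + x[pk + 1]
  delta <- ifelse(abs(den) > .Machine$double.eps, 0.5 * num / den, 0)
  times <- (pk - 1 + clamp(delta, -0.5, 0.5)) / rate
  pp <- diff(times) * 1000
  gate <- rw_constants$pp_gate_ms
  ok <- pp > gate[1] & pp < gate[2]
  structure(list(peak_times = times, pp_intervals = pp[ok],
                 n_gated = sum(!ok)), class = "pulse_series")
}

#' Root mean square of successive pulse-interval differences
#'
#' `sqrt(mean(diff(pp)^2))` over successive peak-to-peak intervals; the
#' time-domain heart-rate-variability statistic computed from the pulse
#' wave. Requires at least three intervals, otherwise `NA`.
#'
#' @param pp Pulse-to-pulse intervals in ms.
#' @return rMSSD in ms.
#' @export
#' @examples
#' rmssd(c(800, 810, 790, 805))  # ~15.55
rmssd <- function(pp) {
  pp <- pp[!is.na(pp)]
  if (length(pp) < 3) return(NA_real_)
  sqrt(mean(diff(pp)^2))
}

#' Band power of a signal by periodogram integration
#'
#' Total power (signal-variance units) contributed by frequencies inside
#' `band`, computed from the one-sided periodogram so that the sum over
#' all bands equals the signal variance (a unit-amplitude in-band sinusoid
#' has band power 1/2). The mean is removed first, making the result
#' invariant to constant offsets.
#'
#' @param x Numeric signal (for HRV use, the evenly resampled tachogram).
#' @param rate Sampling rate, Hz.
#' @param band `c(low, high)` in Hz.
#' @return Band power (units of `x` squared).
#' @export
band_power <- function(x, rate, band) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  x <- x - mean(x)
  p <- Mod(fft(x))^2 / n^2
  k <- seq(2, n %/% 2 + 1)
  f <- (k - 1) * rate / n
  one_sided <- 2 * p[k]
  if (n %% 2 == 0) one_sided[length(k)] <- p[k[length(k)]]
  sum(one_sided[f >= band[1] & f <= band[2]])
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 < .Machine$double.eps) return(0)
  mean(x^4) / m2^2 - 3
}

#' Respiratory rate from a two-channel PPG window
#'
#' Two-source separation of the window: both channels are decimated,
#' whitened, and rotated to the angle maximising non-Gaussianity (absolute
#' excess kurtosis); of the two separated components, the one whose
#' dominant frequency lies in the respiratory band (0.1-0.5 Hz) gives
#' RR = 60 x dominant frequency. When separation yields no respiratory
#' component the band-filtered first channel is used as a fallback, and if
#' the respiratory band holds less than 5 percent of that channel's power
#' the window is marked missing. The result carries a `"source"`
#' attribute (`"ica"`, `"fallback"`, or `"missing"`).
#'
#' @param ppg Tibble or matrix with two channel columns (`ch1`, `ch2`).
#' @param rate Sampling rate, Hz.
#' @return Respiratory rate in breaths/min (`NA` when missing).
#' @export
respiratory_rate <- function(ppg, rate = rw_constants$ppg_rate) {
  m <- as.matrix(ppg[, intersect(c("ch1", "ch2"), colnames(ppg)), drop = FALSE])
  if (ncol(m) < 2) abort("two PPG channels required")
  dec <- max(1L, as.integer(rate / 10))
  fs <- rate / dec
  if (dec > 1) {
    nb <- nrow(m) %/% dec
    m <- apply(m[seq_len(nb * dec), ], 2,
               function(v) colMeans(matrix(v, nrow = dec)))
  }
  band <- rw_constants$resp_band
  m <- sweep(m, 2, colMeans(m))
  cv <- crossprod(m) / nrow(m)
  eg <- eigen(cv, symmetric = TRUE)
  rr <- NA_real_
  src <- "missing"
  if (eg$values[2] > 1e-10 * eg$values[1]) {
    w <- eg$vectors %*% diag(1 / sqrt(eg$values))
    z <- m %*% w
    angles <- seq(0, pi, length.out = 64)
    proj <- z %*% rbind(cos(angles), sin(angles))
    kur <- abs(apply(proj, 2, excess_kurtosis))
    a <- angles[which.max(kur)]
    comps <- cbind(z %*% c(cos(a), sin(a)), z %*% c(-sin(a), cos(a)))
    fdom <- apply(comps, 2, dominant_frequency, rate = fs)
    in_band <- which(!is.na(fdom) & fdom >= band[1] & fdom <= band[2])
    if (length(in_band)) {
      rr <- fdom[in_band[1]] * 60
      src <- "ica"
    }
  } else {
    # degenerate (proportional channels): use the first channel directly
    f <- dominant_frequency(m[, 1], fs)
    if (!is.na(f) && f >= band[1] && f <= band[2]) {
      rr <- f * 60
      src <- "ica"
    }
  }
  if (is.na(rr)) {
    ch1 <- m[, 1]
    tot <- stats::var(ch1)
    bp <- band_power(ch1, fs, band)
    if (is.finite(tot) && tot > 0 && is.finite(bp) && bp / tot >= 0.05) {
      f <- dominant_frequency(ch1, fs)
      if (!is.na(f) && f >= band[1] && f <= band[2]) {
        rr <- f * 60
        src <- "fallback"
      }
    }
  }
  structure(rr, source = src)
}

#' Fit z-score normalisation parameters
#' @param x Numeric training values.
#' @return List `mean`, `sd`.
#' @export
fit_znorm <- function(x) {
  list(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
}

#' Apply z-score normalisation with previously fitted parameters
#'
#' Normalisation always uses the supplied fit (typically estimated on
#' training data) and never refits on the values being transformed.
#'
#' @param x Values to normalise.
#' @param fit Output of [fit_znorm()].
#' @return Normalised values.
#' @export
znormalize <- function(x, fit) {
  if (!is.finite(fit$sd) || fit$sd <= 0) {
    abort("z-normalisation fit has zero or undefined SD")
  }
  (x - fit$mean) / fit$sd
}

#' Detect oxygen-desaturation events
#'
#' The running baseline at time t is the maximum SpO2 over the preceding
#' 120 s. An event starts when SpO2 drops strictly more than 4 percentage
#' points below baseline and ends when it recovers to within 2 points of
#' the (current) baseline or after a 300 s cap. Event depth is the largest
#' drop below the baseline recorded at event start.
#'
#' @param spo2 Tibble with `time` (s) and `spo2` (percent), 1 Hz.
#' @return Tibble `start_time`, `end_time`, `duration`, `depth`.
#' @export
detect_desaturations <- function(spo2) {
  x <- spo2$spo2
  tt <- spo2$time
  n <- length(x)
  look <- rw_constants$desat_baseline_s
  drop <- rw_constants$desat_drop_points
  resume <- rw_constants$desat_resume_points
  cap <- rw_constants$desat_cap_s
  base <- c(x[1], zoo::rollapply(x, width = look, FUN = max,
                                 align = "right", partial = TRUE)[-n])
  events <- list()
  i <- 1
  while (i <= n) {
    if (x[i] < base[i] - drop) {
      b0 <- base[i]
      j <- i
      while (j < n && x[j + 1] < base[j + 1] - resume &&
             tt[j + 1] - tt[i] < cap) {
        j <- j + 1
      }
      events[[length(events) + 1]] <- tibble::tibble(
        start_time = tt[i], end_time = tt[j],
        duration = tt[j] - tt[i] + 1,
        depth = b0 - min(x[i:j])
      )
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(events)) {
    return(tibble::tibble(start_time = double(), end_time = double(),
                          duration = double(), depth = double()))
  }
  dplyr::bind_rows(events)
}

#' Hourly oxygen metrics
#'
#' Per-hour oxygen-desaturation index (events starting in the hour), mean
#' event duration, and the percentage of samples spent at SpO2 >= 95,
#' in [90, 95) and below 90 (the three bands partition every sample, so
#' the percentages sum to 100 per hour).
#'
#' @param spo2 Tibble `time`, `spo2` at 1 Hz.
#' @param events Output of [detect_desaturations()].
#' @param hours Number of hours covered (default 6).
#' @return Tibble `hour` (0-based), `odi`, `od_duration` (s; 0 when the
#'   hour has no events), `spo2_ge95`, `spo2_90_95`, `spo2_lt90`
#'   (percent; NA when the hour has no samples).
#' @export
hourly_oxygen <- function(spo2, events, hours = 6) {
  purrr::map_dfr(seq_len(hours) - 1, function(h) {
    sel <- spo2$time >= h * 3600 & spo2$time < (h + 1) * 3600
    ev <- events$start_time >= h * 3600 & events$start_time < (h + 1) * 3600
    xs <- spo2$spo2[sel]
    if (!length(xs)) {
      return(tibble::tibble(hour = h, odi = NA_real_, od_duration = NA_real_,
                            spo2_ge95 = NA_real_, spo2_90_95 = NA_real_,
                            spo2_lt90 = NA_real_))
    }
    tibble::tibble(
      hour = h,
      odi = sum(ev),
      od_duration = if (any(ev)) mean(events$duration[ev]) else 0,
      spo2_ge95 = 100 * mean(xs >= 95),
      spo2_90_95 = 100 * mean(xs >= 90 & xs < 95),
      spo2_lt90 = 100 * mean(xs < 90)
    )
  })
}

#' Per-30-s nocturnal indicator windows
#'
#' Divides the night into 30-s windows and computes the seven indicators:
#' HR (60000 / mean PP in the window), RR (two-channel respiratory
#' separation), SpO2 (mean of in-window samples), rMSSD (in-window
#' intervals), and LF, HF, LF/HF. The spectral indicators are computed on
#' a 5-min trailing tachogram buffer ending at the window (the LF band is
#' not estimable from 30 s alone), re-evaluated every 30 s so the output
#' stays on the 30-s grid. Windows with fewer than 2 in-window pulses are
#' marked missing.
#'
#' @param pulse A `pulse_series` from [detect_peaks()].
#' @param ppg Two-channel night PPG tibble (`time`, `ch1`, `ch2`), used
#'   for respiratory-rate separation; `NULL` skips RR.
#' @param spo2 Night SpO2 tibble; `NULL` skips SpO2.
#' @param window Window length, s.
#' @param night_seconds Night span, s.
#' @return Tibble with `window_start` and columns `hr`, `rr`, `spo2`,
#'   `rmssd`, `lf`, `hf`, `lf_hf` (one row per window; 720 rows for a
#'   6-h night at 30 s).
#' @export
window_indicators <- function(pulse, ppg = NULL, spo2 = NULL, window = 30,
                              night_seconds = rw_constants$night_seconds) {
  starts <- seq(0, night_seconds - window, by = window)
  trate <- rw_constants$tachogram_rate
  buf <- rw_constants$hrv_buffer_s
  fs <- rw_constants$ppg_rate

  # even tachogram over the whole night, then sliced per trailing buffer
  pt <- pulse$peak_times
  tacho <- NULL
  if (length(pt) > 3) {
    mid <- pt[-length(pt)]
    ppall <- diff(pt) * 1000
    ok <- ppall > rw_constants$pp_gate_ms[1] & ppall < rw_constants$pp_gate_ms[2]
    tg <- seq(0, night_seconds - 1 / trate, by = 1 / trate)
    tacho <- approx(mid[ok], ppall[ok], xout = tg, rule = 2)$y
  }

  rr_all <- rep(NA_real_, length(starts))
  if (!is.null(ppg)) {
    wlen <- as.integer(window * fs)
    nmax <- nrow(ppg)
    rr_all <- vapply(seq_along(starts), function(i) {
      i0 <- as.integer(starts[i] * fs) + 1
      i1 <- min(i0 + wlen - 1, nmax)
      if (i1 - i0 + 1 < wlen / 2) return(NA_real_)
      as.numeric(respiratory_rate(ppg[i0:i1, ], rate = fs))
    }, double(1))
  }

  purrr::map_dfr(seq_along(starts), function(i) {
    s <- starts[i]
    in_w <- pt >= s & pt < s + window
    pp_w <- diff(pt[in_w]) * 1000
    pp_w <- pp_w[pp_w > rw_constants$pp_gate_ms[1] &
                   pp_w < rw_constants$pp_gate_ms[2]]
    hr <- if (length(pp_w) >= 1) 60000 / mean(pp_w) else NA_real_
    rm <- rmssd(pp_w)
    sp <- NA_real_
    if (!is.null(spo2)) {
      sel <- spo2$time >= s & spo2$time < s + window
      if (any(sel)) sp <- mean(spo2$spo2[sel])
    }
    lf <- hf <- lfhf <- NA_real_
    if (!is.null(tacho)) {
      b0 <- max(0, s + window - buf)
      idx <- seq(as.integer(b0 * trate) + 1,
                 as.integer((s + window) * trate))
      seg <- tacho[idx]
      lf <- band_power(seg, trate, rw_constants$lf_band)
      hf <- band_power(seg, trate, rw_constants$hf_band)
      lfhf <- if (is.finite(hf) && hf > 0) lf / hf else NA_real_
    }
    tibble::tibble(window_start = s, hr = hr, rr = rr_all[i], spo2 = sp,
                   rmssd = rm, lf = lf, hf = hf, lf_hf = lfhf)
  })
}
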