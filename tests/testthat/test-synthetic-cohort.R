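test_that("empty cohort and argument validation", {
  coh <- generate_cohort(0, 0, days_per_subject = 5, seed = 1,
                         streams = character())
  expect_s3_class(coh, "wear_cohort")
  expect_equal(nrow(coh$profiles), 0)
  expect_length(coh$recordings, 0)
  expect_error(generate_cohort(-1, 3, seed = 1), "non-negative")
  expect_error(generate_cohort(2, 2), "seed")
})

test_that("generation is deterministic for fixed arguments", {
  a <- generate_cohort(3, 2, days_per_subject = 1, seed = 42,
                       streams = "spo2")
  b <- generate_cohort(3, 2, days_per_subject = 1, seed = 42,
                       streams = "spo2")
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$recordings, b$recordings)
  c <- generate_cohort(3, 2, days_per_subject = 1, seed = 43,
                       streams = "spo2")
  expect_false(identical(a$recordings[[1]]$spo2, c$recordings[[1]]$spo2))
})

test_that("profiles carry the planted group contrasts in their parameters", {
  coh <- generate_cohort(25, 25, days_per_subject = 1, seed = 7,
                         streams = character())
  pars <- dplyr::bind_rows(lapply(coh$profiles$params, tibble::as_tibble))
  pars$group <- coh$profiles$group
  by_grp <- function(col) tapply(pars[[col]], pars$group, mean)
  expect_lt(by_grp("hrv_peak_amplitude")["MCI"],
            by_grp("hrv_peak_amplitude")["control"])
  expect_gt(by_grp("lfhf_jitter")["MCI"], by_grp("lfhf_jitter")["control"])
  expect_gt(by_grp("desat_rate_per_hour")["MCI"],
            by_grp("desat_rate_per_hour")["control"])
  expect_lt(by_grp("high_activity_fraction")["MCI"],
            by_grp("high_activity_fraction")["control"])
  expect_true(all(pars$morning_low_activity_bias[pars$group == "MCI"] > 0))
  expect_true(all(pars$desat_rate_per_hour >= 0))
  expect_true(all(pars$high_activity_fraction >= 0 &
                    pars$high_activity_fraction <= 1))
})

test_that("night streams satisfy the recording invariants", {
  p <- group_defaults("control")
  night <- synth_night_ppg(p, seed = 11)
  expect_equal(nrow(night$ppg), 21600 * 100)
  expect_equal(nrow(night$spo2), 21600)
  expect_true(all(diff(night$ppg$time) > 0))
  expect_true(all(night$spo2$spo2 >= 50 & night$spo2$spo2 <= 100))
})

test_that("rate-zero desaturation Poisson yields no dips", {
  p <- group_defaults("control")
  p$desat_rate_per_hour <- 0
  night <- synth_night_ppg(p, seed = 5)
  base <- max(night$spo2$spo2)
  expect_equal(sum(night$spo2$spo2 < base - 4), 0)
  expect_equal(nrow(attr(night$spo2, "planted_desats")), 0)
})

test_that("respiratory component sits at the requested rate", {
  p <- group_defaults("control")
  p$resp_rate_bpm <- 15
  night <- synth_night_ppg(p, seed = 9, night_seconds = 600)
  # channel 2 is respiration-dominated; dominant in-band frequency = 0.25 Hz
  # (decimated to 10 Hz: a 0.1-0.5 Hz band-pass at 100 Hz is ill-conditioned)
  dec <- colMeans(matrix(night$ppg$ch2[seq_len(60000 - 60000 %% 10)],
                         nrow = 10))
  resp <- bandpass_filter(dec, 10, c(0.1, 0.5))
  f <- rhythmwear:::dominant_frequency(resp, 10, pad = 2^17)
  expect_equal(f, 0.25, tolerance = 0.02)
  # the per-window estimator agrees
  rr <- respiratory_rate(night$ppg[1:3000, ], rate = 100)
  expect_equal(as.numeric(rr), 15, tolerance = 1)
})

test_that("rMSSD curve of a clean control night peaks near 03:00", {
  p <- group_defaults("control")
  p$pp_jitter_ms <- 0  # noise-free night
  night <- synth_night_ppg(p, seed = 21)
  card <- bandpass_filter(night$ppg$ch1, 100, c(0.66, 3))
  ind <- window_indicators(detect_peaks(card), ppg = NULL, spo2 = NULL)
  sm <- compress_curve(ind$rmssd, block = 10)  # 5-min medians
  peak_hour <- (which.max(sm) - 0.5) * 10 * 30 / 3600
  expect_lt(abs(peak_hour - 3), 1)
})

test_that("zero activity scale gives a constant 1 g vertical channel", {
  p <- group_defaults("control")
  p$activity_scale <- 0
  acc <- synth_day_accel(p, seed = 3, day_seconds = 1200)
  expect_equal(acc$z, rep(1, nrow(acc)))
  counts <- accel_to_counts(acc$z - 1)
  expect_true(all(counts == 0))
})

test_that("diurnal template: post-lunch trough below morning peak", {
  expect_lt(activity_template(13.5), activity_template(8.5))
  h <- seq(8, 20, by = 1 / 60)
  tmpl <- activity_template(h)
  expect_equal(h[which.max(tmpl)], 8.6, tolerance = 0.2)
  expect_lt(min(tmpl[h >= 13 & h < 14]), min(tmpl[h >= 8 & h < 12]))
})

test_that("planted activity contrast: MCI has fewer top-decile minutes", {
  coh <- generate_cohort(30, 30, days_per_subject = 2, seed = 7,
                         streams = character())
  # pooled top-decile threshold, then per-subject high-minute fraction
  all_int <- purrr::map(seq_len(nrow(coh$profiles)), function(i) {
    p <- coh$profiles[i, ]
    unlist(lapply(1:2, function(d) {
      synth_minute_intensity(p$params[[1]],
                             seed = rhythmwear:::derive_seed(p$seed, 7, d))
    }))
  })
  thr <- quantile(unlist(all_int), 0.9)
  high_frac <- purrr::map_dbl(all_int, function(v) mean(v >= thr))
  grp <- coh$profiles$group
  expect_lt(mean(high_frac[grp == "MCI"]), mean(high_frac[grp == "control"]))
  wt <- wilcox.test(high_frac[grp == "MCI"], high_frac[grp == "control"],
                    alternative = "less", exact = FALSE)
  expect_lt(wt$p.value, 0.01)
})

test_that("artifact injection records metadata and identity on empty spec", {
  spo2 <- make_spo2_trapezoid(baseline = 97, duration_s = 21600)
  rec <- make_recording(spo2 = spo2)
  expect_identical(inject_artifacts(rec, tibble::tibble()), rec)
  spec <- tibble::tibble(stream = "spo2", type = "null_gap",
                         start_s = 100, duration_s = 60)
  out <- inject_artifacts(rec, spec)
  expect_equal(nrow(out$artifacts), 1)
  expect_true(all(out$spo2$spo2[out$spo2$time >= 100 &
                                  out$spo2$time < 160] == 0))
  bad <- tibble::tibble(stream = "spo2", type = "null_gap",
                        start_s = 21000, duration_s = 2000)
  expect_error(inject_artifacts(rec, bad), "outside")
})
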