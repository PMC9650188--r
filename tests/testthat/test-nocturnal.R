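test_that("peak detection recovers a clean constant-spacing pulse train", {
  tr <- make_pulse_train(spacing_s = 0.8, duration_s = 60)
  ps <- detect_peaks(tr$x - mean(tr$x), rate = 100)
  expect_s3_class(ps, "pulse_series")
  expect_equal(length(ps$peak_times), length(tr$beats))
  expect_true(all(abs(ps$pp_intervals - 800) < 5))
  expect_equal(ps$n_gated, 0L)
})

test_that("a missed beat produces one gated (removed) interval", {
  tr <- make_pulse_train(spacing_s = 1.6, duration_s = 120)
  # remove one pulse: the flanking intervals merge to 3200 ms, outside the
  # physiologic (250, 3000) ms gate
  drop <- tr$beats[30]
  x <- tr$x
  idx <- which(abs(tr$time - drop) < 0.5)
  x[idx] <- 0
  ps <- detect_peaks(x - mean(x), rate = 100)
  expect_equal(ps$n_gated, 1L)
  expect_true(all(ps$pp_intervals < 1700))
})

test_that("zero signal yields an empty pulse series", {
  ps <- detect_peaks(rep(0, 6000), rate = 100)
  expect_length(ps$peak_times, 0)
  expect_length(ps$pp_intervals, 0)
})

test_that("rMSSD matches hand computation and closed forms", {
  expect_equal(rmssd(c(800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 810, 790, 805)),
               sqrt((10^2 + 20^2 + 15^2) / 3), tolerance = 1e-12)
  expect_equal(rmssd(c(800, 810, 790, 805)), 15.546, tolerance = 1e-3)
  # constant step d -> |d|
  expect_equal(rmssd(seq(700, 760, by = 12)), 12)
  expect_true(is.na(rmssd(c(800, 810))))
  # invariant to adding a constant to all intervals
  pp <- c(810, 795, 820, 800, 790)
  expect_equal(rmssd(pp), rmssd(pp + 250))
})

test_that("band power matches the Parseval oracle for pure tones", {
  fs <- 4
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  hf_tone <- sin(2 * pi * 0.3 * tt)
  expect_equal(band_power(hf_tone, fs, c(0.15, 0.4)), 0.5, tolerance = 0.05)
  expect_lt(band_power(hf_tone, fs, c(0.04, 0.15)), 0.025)
  lf_tone <- sin(2 * pi * 0.1 * tt)
  expect_equal(band_power(lf_tone, fs, c(0.04, 0.15)), 0.5, tolerance = 0.05)
  expect_lt(band_power(lf_tone, fs, c(0.15, 0.4)), 0.025)
  expect_equal(band_power(rep(0, 1200), fs, c(0.15, 0.4)), 0)
  # invariant to the signal mean
  expect_equal(band_power(hf_tone + 100, fs, c(0.15, 0.4)),
               band_power(hf_tone, fs, c(0.15, 0.4)))
})

test_that("respiratory rate from a two-channel cardiac/respiratory mixture", {
  fs <- 100
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(2)
  cardiac <- exp(3 * (cos(2 * pi * 1.2 * tt) - 1))
  cardiac <- cardiac - mean(cardiac)
  resp <- sin(2 * pi * 0.25 * tt)
  ppg <- tibble::tibble(ch1 = 1.0 * cardiac + 0.4 * resp,
                        ch2 = 0.5 * cardiac + 1.0 * resp)
  rr <- respiratory_rate(ppg, rate = fs)
  expect_equal(as.numeric(rr), 15, tolerance = 1)
  expect_equal(attr(rr, "source"), "ica")
})

test_that("respiratory rate: pure tone and cardiac-only fallback", {
  fs <- 100
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 0.2 * tt)
  ppg <- tibble::tibble(ch1 = tone, ch2 = tone)
  rr <- respiratory_rate(ppg, rate = fs)
  expect_equal(as.numeric(rr), 12, tolerance = 0.5)

  cardiac <- sin(2 * pi * 1.2 * tt)
  ppg2 <- tibble::tibble(ch1 = cardiac, ch2 = cardiac)
  rr2 <- respiratory_rate(ppg2, rate = fs)
  expect_true(is.na(as.numeric(rr2)))
  expect_equal(attr(rr2, "source"), "missing")
})

test_that("z-normalisation uses the fitted parameters and flags zero SD", {
  x <- c(2, 4, 6, 8)
  fit <- fit_znorm(x)
  z <- znormalize(x, fit)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  # never refits: new values use the training fit
  expect_equal(znormalize(10, fit), (10 - fit$mean) / fit$sd)
  expect_error(znormalize(1, fit_znorm(rep(5, 4))), "SD")
})

test_that("desaturation detection on trapezoid fixtures is exact", {
  none <- make_spo2_trapezoid(baseline = 98, duration_s = 3600)
  ev <- detect_desaturations(none)
  expect_equal(nrow(ev), 0)
  hx <- hourly_oxygen(none, ev, hours = 1)
  expect_equal(hx$spo2_ge95, 100)
  expect_equal(hx$spo2_90_95, 0)
  expect_equal(hx$spo2_lt90, 0)

  one <- make_spo2_trapezoid(baseline = 97,
                             dips = list(list(start = 600, depth = 5)))
  ev1 <- detect_desaturations(one)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$depth, 5)

  # a drop of exactly 4 points is not an event (strictly more than 4)
  four <- make_spo2_trapezoid(baseline = 97,
                              dips = list(list(start = 600, depth = 4)))
  expect_equal(nrow(detect_desaturations(four)), 0)
})

test_that("hourly oxygen metrics partition every sample and count event starts", {
  x <- make_spo2_trapezoid(baseline = 97, duration_s = 7200,
                           dips = list(list(start = 500, depth = 6),
                                       list(start = 1500, depth = 8,
                                            hold = 90),
                                       list(start = 4000, depth = 5)))
  ev <- detect_desaturations(x)
  expect_equal(nrow(ev), 3)
  hx <- hourly_oxygen(x, ev, hours = 2)
  expect_equal(hx$odi, c(2, 1))
  expect_true(all(abs(hx$spo2_ge95 + hx$spo2_90_95 + hx$spo2_lt90 - 100)
                  < 1e-9))
  expect_gt(hx$od_duration[1], 0)
})

test_that("windowed indicators: HR from constant PP and full-night row count", {
  tr <- make_pulse_train(spacing_s = 0.8, duration_s = 21600)
  ps <- detect_peaks(tr$x - mean(tr$x), rate = 100)
  ind <- window_indicators(ps, ppg = NULL, spo2 = NULL)
  expect_equal(nrow(ind), 720)
  expect_equal(median(ind$hr, na.rm = TRUE), 75, tolerance = 0.2)
  # constant spacing -> rMSSD near zero
  expect_lt(median(ind$rmssd, na.rm = TRUE), 2)
})
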