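#' Pipeline constants
#'
#' Fixed processing constants shared across the pipeline: sampling rates,
#' analysis windows, the activity-count mapping, physiological frequency
#' bands, pulse-interval gating and the oxygen-desaturation event rules.
#' Values can be overridden per call where a function exposes them as
#' arguments; this list is the single source of the defaults.
#'
#' @format A named list.
#' @export
rw_constants <- list(
  accel_rate    = 25,     # Hz, daytime tri-axial accelerometer
  ppg_rate      = 100,    # Hz, nocturnal dual-channel PPG
  spo2_rate     = 1,      # Hz, nocturnal SpO2
  day_seconds   = 43200,  # 08:00-20:00 daytime analysis window
  night_seconds = 21600,  # 00:00-06:00 nocturnal analysis window

  # acceleration -> Count mapping (per 1-s block of 30 resampled samples)
  count_rate       = 30,    # Hz after resampling the vertical axis
  count_deadband_g = 0.05,  # |a| at or below this contributes nothing
  count_ceiling_g  = 2,     # excess above deadband is clipped here
  count_resolution = 0.01,  # g*sample per Count unit

  nonwear_minutes = 90,     # strictly more than this many zero-PA minutes
  flatline_frac   = 1e-4,   # channel SD below this fraction of full scale

  cardiac_band = c(0.66, 3.0),  # Hz, 40-180 bpm elderly heart-rate range
  resp_band    = c(0.10, 0.50), # Hz, 6-30 breaths/min
  lf_band      = c(0.04, 0.15), # Hz, tachogram low frequency
  hf_band      = c(0.15, 0.40), # Hz, tachogram high frequency

  pp_gate_ms     = c(250, 3000), # physiologic pulse-interval gate
  refractory_s   = 0.3,          # minimum spacing between detected pulses
  tachogram_rate = 4,            # Hz, evenly resampled PP series
  hrv_buffer_s   = 300,          # trailing buffer for spectral HRV

  desat_drop_points   = 4,   # event starts when SpO2 < baseline - 4 (strict)
  desat_resume_points = 2,   # event ends when SpO2 >= baseline - 2
  desat_cap_s         = 300, # maximum event duration
  desat_baseline_s    = 120  # running-max baseline lookback
)

#' Default circadian generator parameters by group
#'
#' Returns the per-group parameter set used by the synthetic-cohort
#' generator. The constants are calibrated so that the pipeline's nocturnal
#' summaries land in realistic elderly ranges (control rMSSD roughly
#' 70-90 ms, LF/HF near 0.6, ODI around 4 events/h, most of the night spent
#' at SpO2 >= 95 percent), with the MCI group carrying the planted
#' contrasts: a flattened 03:00 HRV peak, larger LF/HF variability, more
#' frequent and deeper desaturations, a lower high-intensity activity
#' fraction and a morning excess of low-activity minutes.
#'
#' @param group `"control"` or `"MCI"`.
#' @return A named list of generator parameters.
#' @export
#' @examples
#' group_defaults("control")$hrv_peak_amplitude
#' group_defaults("MCI")$hrv_peak_amplitude
group_defaults <- function(group = c("control", "MCI")) {
  group <- match.arg(group)
  base <- list(
    mean_hr_bpm        = 68,
    hrv_peak_amplitude = 1.0,   # scales the 03:00 Gaussian bump of HRV depth
    hrv_peak_hour      = 3,
    hrv_hf_amp_ms      = 105,   # respiratory-coupled PP modulation amplitude
    lfhf_mean          = 0.42,  # LF-to-HF squared-amplitude modulation ratio
    lfhf_jitter        = 0.05,  # slow log-normal wobble of LF amplitude
    pp_jitter_ms       = 20,    # broadband beat-to-beat variability
    desat_rate_per_hour = 4.0,
    desat_depth_points  = 6,
    desat_hold_min_s    = 20,   # plateau duration range, seconds
    desat_hold_max_s    = 80,
    high_activity_fraction   = 0.10,
    morning_low_activity_bias = 0,
    activity_scale     = 0.45,  # g, overall oscillation envelope scale
    resp_rate_bpm      = 15,
    ppg_noise_sd       = 0      # additive measurement noise, off by default
  )
  if (group == "MCI") {
    base$mean_hr_bpm         <- 77
    base$hrv_peak_amplitude  <- 0.30
    base$lfhf_jitter         <- 0.25
    base$desat_rate_per_hour <- 5.5
    base$desat_depth_points  <- 6.5
    base$desat_hold_min_s    <- 30
    base$desat_hold_max_s    <- 120
    base$high_activity_fraction    <- 0.06
    base$morning_low_activity_bias <- 0.35
  }
  base
}

# Between-subject standard deviations applied around the group defaults.
subject_sds <- list(
  mean_hr_bpm        = 3,
  hrv_peak_amplitude = 0.08,
  hrv_hf_amp_ms      = 10,
  lfhf_jitter        = 0.02,
  desat_rate_per_hour = 0.8,
  desat_depth_points  = 0.4,
  high_activity_fraction = 0.02,
  resp_rate_bpm      = 1
)

# HRV modulation depth over the night: a baseline plus a Gaussian bump at
# the peak hour whose height is the profile's hrv_peak_amplitude.
hrv_depth_curve <- function(hour, peak_amplitude, peak_hour = 3, width_h = 1.2) {
  0.55 + 0.45 * peak_amplitude * exp(-((hour - peak_hour)^2) / (2 * width_h^2))
}

# Diurnal activity-intensity template on [8, 20) hours, max-normalised to 1:
# morning peak at ~08:40, post-lunch trough at 13:00-14:00, evening rebound.
activity_template <- function(hour) {
  raw <- 0.10 +
    0.80 * exp(-((hour - 8.6)^2) / (2 * 0.7^2)) +
    0.35 * exp(-((hour - 10.8)^2) / (2 * 1.6^2)) +
    0.50 * exp(-((hour - 18.0)^2) / (2 * 1.1^2))
  raw / 1.05
}
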