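# Cohort directory format: one directory per subject with delimited text
# per stream (ISO-8601 timestamp column), a cohort manifest CSV and a
# key-value generation config.

iso_time <- function(day_index, seconds, origin_hour) {
  base <- as.POSIXct(sprintf("2021-01-%02d 00:00:00", day_index),
                     tz = "UTC") + origin_hour * 3600
  format(base + seconds, "%Y-%m-%dT%H:%M:%OS2Z")
}

#' Write a cohort to a directory of delimited text files
#'
#' Writes `manifest.csv` (subject id, group, scale features, seed),
#' `config.txt` (key = value generation settings) and one directory per
#' subject containing per-stream CSVs with an ISO-8601 timestamp column.
#'
#' @param cohort A `wear_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wear_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dplyr::select(cohort$profiles, -"params")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("seed = %s", cohort$seed),
               sprintf("n_subjects = %d", nrow(cohort$profiles)),
               sprintf("generated = %s", "rhythmwear synthetic cohort")),
             file.path(dir, "config.txt"))
  for (rec in cohort$recordings) {
    sdir <- file.path(dir, rec$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    tag <- sprintf("day%02d", rec$day_index)
    if (!is.null(rec$accel)) {
      out <- dplyr::mutate(rec$accel,
                           timestamp = iso_time(rec$day_index, .data$time, 8),
                           .before = 1)
      utils::write.csv(dplyr::select(out, -"time"),
                       file.path(sdir, paste0("accel_", tag, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(rec$ppg)) {
      out <- dplyr::mutate(rec$ppg,
                           timestamp = iso_time(rec$day_index, .data$time, 0),
                           .before = 1)
      utils::write.csv(dplyr::select(out, -"time"),
                       file.path(sdir, paste0("ppg_", tag, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(rec$spo2)) {
      out <- dplyr::mutate(rec$spo2,
                           timestamp = iso_time(rec$day_index, .data$time, 0),
                           .before = 1)
      utils::write.csv(dplyr::select(out, -"time"),
                       file.path(sdir, paste0("spo2_", tag, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

parse_iso <- function(ts, origin_hour) {
  t0 <- as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  day0 <- as.POSIXct(format(t0[1], "%Y-%m-%d"), tz = "UTC")
  as.numeric(difftime(t0, day0 + origin_hour * 3600, units = "secs"))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `profiles` (manifest tibble) and `recordings`.
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "manifest.csv")))
  recordings <- list()
  for (sid in manifest$subject_id) {
    sdir <- file.path(dir, sid)
    files <- list.files(sdir, pattern = "\\.csv$")
    days <- unique(sub(".*day(\\d+)\\.csv", "\\1", files))
    for (d in days) {
      rec <- list(subject_id = sid, day_index = as.integer(d),
                  accel = NULL, ppg = NULL, spo2 = NULL, diary = NULL,
                  artifacts = tibble::tibble())
      for (st in c("accel", "ppg", "spo2")) {
        f <- file.path(sdir, sprintf("%s_day%s.csv", st, d))
        if (!file.exists(f)) next
        dat <- tibble::as_tibble(utils::read.csv(f))
        dat$time <- parse_iso(dat$timestamp, if (st == "accel") 8 else 0)
        rec[[st]] <- dplyr::select(dat, "time",
                                   dplyr::everything(), -"timestamp")
      }
      recordings[[length(recordings) + 1]] <- structure(
        rec, class = "raw_recording")
    }
  }
  list(profiles = manifest, recordings = recordings)
}
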