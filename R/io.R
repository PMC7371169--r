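# Plain-text file formats: recordings and label tracks as RFC-4180 CSV,
# datasets as a directory with one manifest CSV, reports as JSON.

#' Write / read a recording CSV
#'
#' Layout: header `t,ax,ay,az,gx,gy,gz,roll,pitch,yaw`; time in seconds,
#' acceleration in g, angular rate in rad/s, attitude angles in rad.
#'
#' @param recording an `inertial_recording` (see [generate_recording()]).
#' @param path file path.
#' @return `write_recording`: the path, invisibly.
#' @export
write_recording <- function(recording, path) {
  utils::write.csv(as.data.frame(recording), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param expected_rate if non-NULL, the sampling rate implied by the file
#'   (median time step) must match within 1%.
#' @return `read_recording`: an `inertial_recording` data.frame.
#' @export
read_recording <- function(path, expected_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  want <- c("t", CHANNELS9)
  if (!identical(names(df), want))
    ethocv_stop("ethocv_channel_error",
                "expected 10 columns (%s); found: %s",
                paste(want, collapse = ","), paste(names(df), collapse = ","))
  if (any(diff(df$t) <= 0))
    ethocv_stop("ethocv_time_error",
                "time must be strictly increasing (first violation at row %d)",
                which(diff(df$t) <= 0)[1] + 1)
  rate <- 1 / stats::median(diff(df$t))
  if (!is.null(expected_rate) && abs(rate - expected_rate) / expected_rate > 0.01)
    ethocv_stop("ethocv_rate_error",
                "sampling rate %.3f Hz differs from expected %.3f Hz by > 1%%",
                rate, expected_rate)
  class(df) <- c("inertial_recording", "data.frame")
  attr(df, "rate") <- rate
  df
}

#' Write / read a label track CSV
#'
#' Layout: `start_s,end_s,behaviour`, one half-open interval `[start, end)`
#' per row, seconds.
#'
#' @param labels a `label_track` data.frame.
#' @param path file path.
#' @return `write_labels`: the path, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @param recording_duration if non-NULL, intervals are clipped to
#'   `[0, recording_duration]` and empty remainders dropped.
#' @param classes allowed behaviour names.
#' @return `read_labels`: a sorted, validated `label_track`.
#' @export
read_labels <- function(path, recording_duration = NULL,
                        classes = ethogram_classes()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("start_s", "end_s", "behaviour")))
    ethocv_stop("ethocv_channel_error",
                "label file must have columns start_s,end_s,behaviour")
  validate_label_track(df, recording_duration, classes)
}

# Shared validation for labels read from disk or built in code.
validate_label_track <- function(df, recording_duration = NULL,
                                 classes = ethogram_classes()) {
  bad <- setdiff(df$behaviour, classes)
  if (length(bad))
    ethocv_stop("ethocv_class_error", "unknown behaviour class(es): %s",
                paste(unique(bad), collapse = ", "))
  if (any(df$end_s <= df$start_s))
    ethocv_stop("ethocv_validation_error", "intervals must have end > start")
  df <- df[order(df$start_s), , drop = FALSE]
  if (nrow(df) > 1) {
    ov <- which(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-12)
    if (length(ov))
      ethocv_stop("ethocv_overlap_error",
                  "overlapping label intervals: [%g, %g) '%s' and [%g, %g) '%s'",
                  df$start_s[ov[1]], df$end_s[ov[1]], df$behaviour[ov[1]],
                  df$start_s[ov[1] + 1], df$end_s[ov[1] + 1],
                  df$behaviour[ov[1] + 1])
  }
  if (!is.null(recording_duration)) {
    df$start_s <- pmax(df$start_s, 0)
    df$end_s <- pmin(df$end_s, recording_duration)
    df <- df[df$end_s > df$start_s, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("label_track", "data.frame")
  df
}

#' Write a cohort to disk as a dataset directory
#'
#' Writes one recording CSV and one label CSV per individual plus a
#' `manifest.csv` with columns `individual_id,group_id,recording,labels,`
#' `sampling_rate` (paths relative to the directory).
#'
#' @param cohort a [generate_cohort()] result (or a list of such results
#'   concatenated across groups).
#' @param dir output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(ind) {
    meta <- attr(ind$recording, "meta")
    id <- meta$individual_id
    rec_file <- sprintf("%s_recording.csv", id)
    lab_file <- sprintf("%s_labels.csv", id)
    write_recording(ind$recording, file.path(dir, rec_file))
    write_labels(ind$labels, file.path(dir, lab_file))
    data.frame(individual_id = id, group_id = meta$group_id,
               recording = rec_file, labels = lab_file,
               sampling_rate = meta$sampling_rate)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return Data.frame of class `dataset_manifest` with absolute paths.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path))
    ethocv_stop("ethocv_validation_error", "no manifest.csv in %s", dir)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "group_id", "recording", "labels",
            "sampling_rate")
  if (!all(need %in% names(mf)))
    ethocv_stop("ethocv_validation_error", "manifest must have columns %s",
                paste(need, collapse = ","))
  if (anyDuplicated(mf$individual_id))
    ethocv_stop("ethocv_validation_error",
                "duplicate individual_id in manifest")
  mf$recording <- file.path(dir, mf$recording)
  mf$labels <- file.path(dir, mf$labels)
  missing <- c(mf$recording, mf$labels)[!file.exists(c(mf$recording,
                                                       mf$labels))]
  if (length(missing))
    ethocv_stop("ethocv_validation_error", "missing dataset file(s): %s",
                paste(missing, collapse = ", "))
  class(mf) <- c("dataset_manifest", "data.frame")
  mf
}

#' Read a plain key = value configuration file
#'
#' Lines of `key = value`; `#` starts a comment; values that parse as
#' numbers become numeric, comma-separated values become vectors.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      ethocv_stop("ethocv_validation_error", "config line without '=': %s", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Log a resolved run configuration
#'
#' Every pipeline run records the configuration it actually used plus the
#' master seed, as JSON, so results are attributable and repeatable.
#'
#' @param dir output directory.
#' @param config named list of resolved settings.
#' @param seed master seed of the run.
#' @return The log path, invisibly.
#' @export
write_run_log <- function(dir, config, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "run_log.json")
  jsonlite::write_json(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                            seed = seed, config = config),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
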