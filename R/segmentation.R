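# Windowing of labelled recordings. Each continuous labelled interval is
# clipped by clip_s at both ends (to absorb annotation error at behaviour
# transitions) and cut into sliding windows of window_s seconds every
# step_s seconds. A window whose end coincides exactly with the clipped
# interval end is admitted.

#' Segmentation configuration
#'
#' @param clip_s seconds clipped from both ends of every labelled interval
#'   (default 1).
#' @param window_s window length in seconds (default 1.3).
#' @param step_s step between window starts in seconds (default 0.5,
#'   must be <= window_s).
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(clip_s = 1.0, window_s = 1.3, step_s = 0.5) {
  if (!all(vapply(list(clip_s, window_s, step_s), is_scalar_num, TRUE)) ||
      clip_s <= 0 || window_s <= 0 || step_s <= 0)
    ethocv_stop("ethocv_validation_error",
                "clip_s, window_s, step_s must all be > 0")
  if (step_s > window_s)
    ethocv_stop("ethocv_validation_error", "step_s must be <= window_s")
  structure(list(clip_s = clip_s, window_s = window_s, step_s = step_s),
            class = "segmentation_config")
}

#' Number of windows in an interval of length L
#'
#' Closed form: `floor((L - 2*clip_s - window_s) / step_s) + 1` when
#' `L >= 2*clip_s + window_s`, else 0. A small epsilon guards the inclusive
#' boundary (e.g. L = 3.3 s with defaults yields exactly one window)
#' against floating-point rounding.
#'
#' @param L interval length in seconds (vectorized).
#' @param config a [segmentation_config()].
#' @return Integer vector of window counts.
#' @export
count_windows <- function(L, config = segmentation_config()) {
  core <- L - 2 * config$clip_s - config$window_s
  ifelse(core >= -1e-9, floor((core + 1e-9) / config$step_s) + 1, 0L)
}

#' Windows of one labelled interval
#'
#' @param recording an `inertial_recording`.
#' @param start_s,end_s the interval (half-open, seconds); must lie within
#'   the recording.
#' @param behaviour the interval's label, attached to every window.
#' @param config a [segmentation_config()].
#' @param rate sampling rate (Hz); default inferred from the time column.
#' @return List with `info` (data.frame behaviour/start_s) and `samples`
#'   (array n_windows x samples_per_window x 9). Short intervals yield
#'   zero windows, not an error.
#' @export
clip_and_window <- function(recording, start_s, end_s, behaviour,
                            config = segmentation_config(), rate = NULL) {
  rate <- rate %||% (1 / stats::median(diff(recording$t)))
  spw <- round(config$window_s * rate)  # samples per window
  n_win <- count_windows(end_s - start_s, config)
  if (n_win <= 0)
    return(list(info = data.frame(behaviour = character(0),
                                  start_s = numeric(0)),
                samples = array(0, c(0, spw, 9))))
  starts <- start_s + config$clip_s + (seq_len(n_win) - 1) * config$step_s
  X <- as.matrix(recording[, CHANNELS9])
  t0 <- recording$t[1]
  samples <- array(NA_real_, c(n_win, spw, 9),
                   dimnames = list(NULL, NULL, CHANNELS9))
  for (w in seq_len(n_win)) {
    i0 <- round((starts[w] - t0) * rate) + 1
    if (i0 < 1 || i0 + spw - 1 > nrow(X))
      ethocv_stop("ethocv_validation_error",
                  "window [%g, %g) falls outside the recording",
                  starts[w], starts[w] + config$window_s)
    samples[w, , ] <- X[i0:(i0 + spw - 1), ]
  }
  list(info = data.frame(behaviour = behaviour, start_s = starts,
                         stringsAsFactors = FALSE),
       samples = samples)
}

#' Windows of a whole dataset
#'
#' Applies [clip_and_window()] to every labelled interval of every
#' individual, concatenating in a stable order (individual, interval,
#' start time).
#'
#' @param x a `cohort` (see [generate_cohort()]), a plain list of
#'   `list(recording, labels)` entries, or a dataset directory path
#'   readable by [read_manifest()].
#' @param config a [segmentation_config()].
#' @return Object of class `window_set`: list with `info` (data.frame
#'   individual_id, group_id, behaviour, interval_id, start_s) and
#'   `samples` (n x samples_per_window x 9 array), plus `rate` and
#'   `config`. Errors if no window survives.
#' @export
dataset_windows <- function(x, config = segmentation_config()) {
  if (is.character(x)) {
    mf <- read_manifest(x)
    x <- lapply(seq_len(nrow(mf)), function(i) {
      rec <- read_recording(mf$recording[i], expected_rate = mf$sampling_rate[i])
      dur <- rec$t[nrow(rec)] + 1 / mf$sampling_rate[i]
      labs <- read_labels(mf$labels[i], recording_duration = dur)
      meta <- recording_meta(mf$individual_id[i], mf$group_id[i],
                             mf$sampling_rate[i])
      attr(rec, "meta") <- meta
      list(recording = rec, labels = labs)
    })
  }
  infos <- list(); chunks <- list(); n_dropped <- 0L
  for (ind in x) {
    meta <- attr(ind$recording, "meta")
    rate <- meta$sampling_rate
    for (k in seq_len(nrow(ind$labels))) {
      w <- clip_and_window(ind$recording, ind$labels$start_s[k],
                           ind$labels$end_s[k], ind$labels$behaviour[k],
                           config, rate = rate)
      if (nrow(w$info) == 0) { n_dropped <- n_dropped + 1L; next }
      w$info$individual_id <- meta$individual_id
      w$info$group_id <- meta$group_id
      w$info$interval_id <- k
      infos[[length(infos) + 1]] <- w$info
      chunks[[length(chunks) + 1]] <- w$samples
    }
  }
  if (!length(infos))
    ethocv_stop("ethocv_empty_error",
                "segmentation produced no windows (all intervals too short)")
  info <- do.call(rbind, infos)
  spw <- dim(chunks[[1]])[2]
  samples <- array(0, c(nrow(info), spw, 9),
                   dimnames = list(NULL, NULL, CHANNELS9))
  at <- 1L
  for (ch in chunks) {
    samples[at:(at + dim(ch)[1] - 1), , ] <- ch
    at <- at + dim(ch)[1]
  }
  ord <- order(info$individual_id, info$interval_id, info$start_s)
  info <- info[ord, c("individual_id", "group_id", "behaviour",
                      "interval_id", "start_s")]
  rownames(info) <- NULL
  structure(list(info = info, samples = samples[ord, , , drop = FALSE],
                 rate = attr(x[[1]]$recording, "meta")$sampling_rate,
                 config = config, n_short_intervals = n_dropped),
            class = "window_set")
}
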