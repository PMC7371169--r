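# Window -> feature-vector mapping. The default registry is a standard
# inertial-classification set: per-channel moments, within-sensor axis
# correlations, signal magnitude area, and the dominant periodogram
# frequency of the acceleration magnitude. The registry is pluggable so an
# alternative feature space can be swapped in without touching the rest of
# the pipeline.

#' Default feature registry
#'
#' 54 features per window:
#' \itemize{
#'   \item per channel (9): mean, standard deviation, minimum, maximum,
#'     root-mean-square (45);
#'   \item pairwise Pearson correlations within the accelerometer axes and
#'     within the gyroscope axes (6); zero-variance channels give 0;
#'   \item signal magnitude area of acceleration,
#'     `mean(|ax| + |ay| + |az|)` (1);
#'   \item dominant periodogram frequency (Hz) of the mean-removed
#'     acceleration magnitude and its power (2).
#' }
#'
#' @return Named list of functions `f(W, rate)` mapping a
#'   samples-by-9-channels window matrix to a named numeric vector.
#' @export
default_feature_registry <- function() {
  list(
    moments = function(W, rate) {
      stats <- c(mean = mean, sd = stats::sd, min = min, max = max,
                 rms = function(v) sqrt(mean(v^2)))
      out <- vapply(colnames(W), function(ch)
        vapply(stats, function(f) f(W[, ch]), 0.0), numeric(5))
      v <- as.vector(out)
      names(v) <- as.vector(outer(names(stats), colnames(W),
                                  function(s, ch) paste(ch, s, sep = "_")))
      v
    },
    correlations = function(W, rate) {
      pairs <- list(c("ax", "ay"), c("ax", "az"), c("ay", "az"),
                    c("gx", "gy"), c("gx", "gz"), c("gy", "gz"))
      v <- vapply(pairs, function(p) {
        a <- W[, p[1]]; b <- W[, p[2]]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
      }, 0.0)
      names(v) <- vapply(pairs, function(p) paste0("cor_", p[1], "_", p[2]), "")
      v
    },
    sma = function(W, rate)
      c(sma_acc = mean(abs(W[, "ax"]) + abs(W[, "ay"]) + abs(W[, "az"]))),
    spectral = function(W, rate) {
      m <- sqrt(W[, "ax"]^2 + W[, "ay"]^2 + W[, "az"]^2)
      p <- periodogram(m, rate)
      k <- which.max(p$power)
      c(dom_freq_acc = p$freq[k], dom_power_acc = p$power[k])
    }
  )
}

# One-sided periodogram of a mean-removed series, DC excluded.
periodogram <- function(x, rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  k <- seq_len(floor(n / 2))
  list(freq = k * rate / n, power = sp[k + 1])
}

#' Extract the feature vector of one window
#'
#' @param W samples-by-9 window matrix with channel column names.
#' @param rate sampling rate in Hz.
#' @param registry feature registry, default [default_feature_registry()].
#' @param expected_samples if non-NULL, `W` must have exactly this many
#'   rows.
#' @return Named numeric feature vector (54 features with the default
#'   registry).
#' @export
extract_features <- function(W, rate, registry = default_feature_registry(),
                             expected_samples = NULL) {
  if (!is.null(expected_samples) && nrow(W) != expected_samples)
    ethocv_stop("ethocv_validation_error",
                "window has %d samples, expected %d", nrow(W),
                expected_samples)
  if (nrow(W) < 4)
    ethocv_stop("ethocv_validation_error", "window too short (%d samples)",
                nrow(W))
  unlist(unname(lapply(registry, function(f) f(W, rate))))
}

#' Build a feature dataset from a window set
#'
#' Rows follow the window set's canonical order (individual, interval,
#' start time), so permuting the generation order of windows does not
#' change the matrix.
#'
#' @param windows a `window_set` from [dataset_windows()].
#' @param registry feature registry.
#' @return Object of class `feature_dataset`: list with `features`
#'   (numeric matrix with named columns), `labels`, `individual_id`,
#'   `group_id` (character vectors) and `feature_names`.
#' @export
build_feature_dataset <- function(windows,
                                  registry = default_feature_registry()) {
  stopifnot(inherits(windows, "window_set"))
  n <- nrow(windows$info)
  if (n == 0)
    ethocv_stop("ethocv_empty_error", "no windows to featurize")
  # canonical row order (individual, interval, start), independent of the
  # order windows were produced in
  ord <- order(windows$info$individual_id, windows$info$interval_id,
               windows$info$start_s)
  windows$info <- windows$info[ord, , drop = FALSE]
  windows$samples <- windows$samples[ord, , , drop = FALSE]
  rows <- lapply(seq_len(n), function(i)
    extract_features(windows$samples[i, , ], windows$rate, registry))
  p <- length(rows[[1]])
  if (!all(vapply(rows, length, 0L) == p))
    ethocv_stop("ethocv_validation_error", "inconsistent feature lengths")
  features <- do.call(rbind, rows)
  if (anyNA(features))
    ethocv_stop("ethocv_validation_error", "NA in feature matrix")
  if (anyDuplicated(colnames(features)))
    ethocv_stop("ethocv_validation_error", "duplicate feature names")
  structure(list(features = features,
                 labels = windows$info$behaviour,
                 individual_id = windows$info$individual_id,
                 group_id = windows$info$group_id,
                 feature_names = colnames(features)),
            class = "feature_dataset")
}

#' Subset the rows of a feature dataset
#'
#' @param ds a `feature_dataset`.
#' @param idx row indices (integer or logical).
#' @return A `feature_dataset` with the selected rows.
#' @export
subset_rows <- function(ds, idx) {
  stopifnot(inherits(ds, "feature_dataset"))
  structure(list(features = ds$features[idx, , drop = FALSE],
                 labels = ds$labels[idx],
                 individual_id = ds$individual_id[idx],
                 group_id = ds$group_id[idx],
                 feature_names = ds$feature_names),
            class = "feature_dataset")
}

#' Combine feature datasets by rows
#'
#' @param ... `feature_dataset` objects with identical feature names.
#' @return A single `feature_dataset`.
#' @export
bind_feature_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1 && is.list(dss[[1]]) &&
      !inherits(dss[[1]], "feature_dataset")) dss <- dss[[1]]
  stopifnot(length(dss) >= 1)
  fn <- dss[[1]]$feature_names
  for (d in dss)
    if (!identical(d$feature_names, fn))
      ethocv_stop("ethocv_validation_error", "feature name mismatch")
  structure(list(features = do.call(rbind, lapply(dss, `[[`, "features")),
                 labels = unlist(lapply(dss, `[[`, "labels"), use.names = FALSE),
                 individual_id = unlist(lapply(dss, `[[`, "individual_id"),
                                        use.names = FALSE),
                 group_id = unlist(lapply(dss, `[[`, "group_id"),
                                   use.names = FALSE),
                 feature_names = fn),
            class = "feature_dataset")
}

#' Fit / apply feature standardization
#'
#' The RBF kernel is scale sensitive, so features are z-scored before
#' classification. Scaling parameters must be fitted on training rows only;
#' [cross_validate()] refits them inside every fold.
#'
#' @param features numeric matrix (training rows).
#' @return `standardizer_fit`: list with per-column `center` and `scale`
#'   (zero-variance columns get scale 1).
#' @export
standardizer_fit <- function(features) {
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

#' @rdname standardizer_fit
#' @param scaler a `standardizer_fit()` result.
#' @return `standardizer_apply`: the standardized matrix.
#' @export
standardizer_apply <- function(features, scaler) {
  sweep(sweep(features, 2, scaler$center), 2, scaler$scale, `/`)
}

#' Export a feature dataset as CSV
#'
#' Header = feature names plus `label`, `individual_id`, `group_id`.
#'
#' @param ds a `feature_dataset`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_feature_dataset <- function(ds, path) {
  df <- data.frame(ds$features, label = ds$labels,
                   individual_id = ds$individual_id, group_id = ds$group_id,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
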