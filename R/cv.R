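# Cross-validation strategies and hyperparameter search.
#
# The per-individual strategy (leave-one-subject-out at the level of whole
# animals) is the honest estimate of performance on unseen individuals:
# each fold tests every window of exactly one animal never seen in
# training. The random strategy splits windows at random, so the same
# animal contributes to both sides — on per-individual-correlated data it
# overestimates accuracy.

#' Cross-validation configuration for the random strategy
#'
#' @param strategy `"random"` (repeated random test fractions) or
#'   `"per_individual"`.
#' @param test_fraction test share for random splits, in (0, 1),
#'   default 0.30.
#' @param n_repeats number of random splits (default 7, matching the
#'   number of per-individual folds of a 7-animal group).
#' @param mode `"split"` for repeated 70/30 splits, `"kfold"` for k-fold
#'   partitioning (k = `n_repeats`); both variants are in use in the
#'   field, so the mode is recorded in every report.
#' @param seed integer seed fixing the splits.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(strategy = c("random", "per_individual"),
                      test_fraction = 0.30, n_repeats = 7L,
                      mode = c("split", "kfold"), seed = 1L) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  if (!is_scalar_num(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1)
    ethocv_stop("ethocv_validation_error", "test_fraction must be in (0, 1)")
  stopifnot(n_repeats >= 1)
  structure(list(strategy = strategy, test_fraction = test_fraction,
                 n_repeats = as.integer(n_repeats), mode = mode,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Per-individual (leave-one-subject-out) folds
#'
#' One fold per individual; the fold's test set is all of that animal's
#' rows, its training set everything else. Test sets are disjoint and
#' cover the dataset.
#'
#' @param dataset a `feature_dataset` with >= 2 individuals.
#' @return List of folds, each `list(train, test, id)` with integer row
#'   indices; class `cv_folds`.
#' @export
make_individual_folds <- function(dataset) {
  stopifnot(inherits(dataset, "feature_dataset"))
  ids <- unique(dataset$individual_id)
  if (length(ids) < 2)
    ethocv_stop("ethocv_validation_error",
                "per-individual CV needs >= 2 individuals (got %d)",
                length(ids))
  folds <- lapply(ids, function(id) {
    test <- which(dataset$individual_id == id)
    list(train = setdiff(seq_along(dataset$labels), test), test = test,
         id = id)
  })
  structure(folds, class = "cv_folds", strategy = "per_individual")
}

#' Random folds
#'
#' In `"split"` mode, `n_repeats` independent splits holding out
#' `test_fraction` of the rows; in `"kfold"` mode, one random partition
#' into `n_repeats` folds.
#'
#' @param dataset a `feature_dataset`.
#' @param config a [cv_config()].
#' @return List of folds as in [make_individual_folds()].
#' @export
make_random_folds <- function(dataset, config = cv_config()) {
  stopifnot(inherits(dataset, "feature_dataset"),
            inherits(config, "cv_config"))
  n <- length(dataset$labels)
  if (n == 0) ethocv_stop("ethocv_empty_error", "empty dataset")
  folds <- with_seed(config$seed, {
    if (config$mode == "kfold") {
      assign <- sample(rep_len(seq_len(config$n_repeats), n))
      lapply(seq_len(config$n_repeats), function(f) {
        test <- which(assign == f)
        list(train = which(assign != f), test = test,
             id = sprintf("kfold_%d", f))
      })
    } else {
      n_test <- round(n * config$test_fraction)
      if (n_test == 0 || n_test == n)
        ethocv_stop("ethocv_validation_error",
                    "test_fraction %.2f leaves an empty side for n = %d",
                    config$test_fraction, n)
      lapply(seq_len(config$n_repeats), function(f) {
        test <- sort(sample.int(n, n_test))
        list(train = setdiff(seq_len(n), test), test = test,
             id = sprintf("split_%d", f))
      })
    }
  })
  empty <- vapply(folds, function(f)
    length(f$test) == 0 || length(f$train) == 0, TRUE)
  if (any(empty))
    ethocv_stop("ethocv_validation_error", "fold with an empty side")
  structure(folds, class = "cv_folds", strategy = paste0("random_",
                                                         config$mode))
}

#' Cross-validate one hyperparameter setting
#'
#' Per fold: fit the classifier on the training rows with fold-local
#' feature standardization, predict the test rows, and score. For
#' `metric = "threshold"` the probability threshold is chosen to maximize
#' the mean threshold accuracy across folds (candidates from
#' `threshold_cfg`); per-fold values are reported at that common
#' threshold. The 95% confidence interval over folds uses the normal
#' approximation `mean +/- 1.96 sd/sqrt(n)` (`ci = "t"` switches to the
#' small-sample t quantile).
#'
#' @param dataset a `feature_dataset`.
#' @param params a [hyper_params()].
#' @param folds a `cv_folds` list.
#' @param metric `"overall"` or `"threshold"`.
#' @param threshold_cfg a [threshold_config()] (threshold metric only).
#' @param seed seed forwarded to the classifier's calibration.
#' @param ci `"normal"` or `"t"`.
#' @param prob_folds calibration folds forwarded to [svm_fit()].
#' @return Object of class `evaluation_report`: per-fold values, mean,
#'   95% CI, chosen threshold (if any), accumulated confusion matrix,
#'   chance level (1/K) and the empirical majority-class baseline.
#' @export
cross_validate <- function(dataset, params, folds,
                           metric = c("overall", "threshold"),
                           threshold_cfg = threshold_config(), seed = 1L,
                           ci = c("normal", "t"), prob_folds = 3L) {
  metric <- match.arg(metric)
  ci <- match.arg(ci)
  stopifnot(inherits(folds, "cv_folds"))
  classes <- sort(unique(dataset$labels))
  fold_overall <- numeric(length(folds))
  preds_all <- character(0); truth_all <- character(0)
  # both metrics are always tallied; `metric` picks which one is reported
  fold_thr <- matrix(NA_real_, length(folds),
                     length(threshold_cfg$thresholds))

  for (k in seq_along(folds)) {
    f <- folds[[k]]
    # leakage guard: per-individual folds must never share an animal
    if (attr(folds, "strategy") == "per_individual" &&
        length(intersect(dataset$individual_id[f$train],
                         dataset$individual_id[f$test])))
      ethocv_stop("ethocv_leakage_error",
                  "fold '%s' shares individuals across train/test", f$id)
    train <- subset_rows(dataset, f$train)
    if (length(unique(train$labels)) < 2)
      ethocv_stop("ethocv_single_class_error",
                  "training side of fold '%s' has < 2 classes", f$id)
    model <- svm_fit(train, params, seed = derive_seed(seed, k),
                     prob_folds = prob_folds)
    test <- subset_rows(dataset, f$test)
    P <- predict_proba(model, test)
    pred <- proba_argmax(P, model$classes)
    fold_overall[k] <- overall_accuracy(pred, test$labels)
    fold_thr[k, ] <- vapply(threshold_cfg$thresholds, function(tau)
      threshold_accuracy(threshold_counts(P, pred, test$labels, tau)), 0.0)
    preds_all <- c(preds_all, pred)
    truth_all <- c(truth_all, test$labels)
  }

  thr_means <- colMeans(fold_thr)
  best <- which.max(thr_means)  # ties -> smallest tau
  chosen_tau <- threshold_cfg$thresholds[best]
  values <- if (metric == "threshold") fold_thr[, best] else fold_overall

  m <- mean(values)
  s <- stats::sd(values)
  q <- if (ci == "t" && length(values) > 1)
    stats::qt(0.975, length(values) - 1) else stats::qnorm(0.975)
  half <- if (length(values) > 1) q * s / sqrt(length(values)) else 0
  counts <- confusion_counts(preds_all, truth_all, classes = classes)

  structure(list(metric = metric, fold_values = values,
                 fold_overall = fold_overall,
                 fold_threshold = fold_thr[, best],
                 mean = m, ci = c(lower = m - half, upper = m + half),
                 ci_method = ci,
                 mean_overall = mean(fold_overall),
                 mean_threshold = thr_means[best],
                 chosen_params = params, chosen_threshold = chosen_tau,
                 threshold_table = data.frame(
                   tau = threshold_cfg$thresholds, mean_value = thr_means),
                 confusion_counts = counts,
                 confusion = normalize_confusion(counts),
                 classes = classes, n_folds = length(folds),
                 strategy = attr(folds, "strategy"),
                 chance_level = 1 / length(classes),
                 majority_baseline = max(table(dataset$labels)) /
                   length(dataset$labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s, %s): %d folds\n", x$metric, x$strategy,
              x$n_folds))
  cat(sprintf("  mean %s accuracy: %.3f  (95%% CI %.3f - %.3f)\n",
              x$metric, x$mean, x$ci["lower"], x$ci["upper"]))
  if (!is.null(x$chosen_threshold))
    cat(sprintf("  chosen threshold: %.1f\n", x$chosen_threshold))
  cat(sprintf("  chance level 1/K: %.3f; majority baseline: %.3f\n",
              x$chance_level, x$majority_baseline))
  invisible(x)
}

#' Hyperparameter grid search
#'
#' Cross-validates every (C, gamma) of the grid with the given folds and
#' metric; for the threshold metric the probability threshold is optimized
#' within each grid point. Ties go to the smallest C, then the smallest
#' gamma. The full grid table is part of the result and can be persisted
#' with [write_grid_table()].
#'
#' @param dataset a `feature_dataset`.
#' @param grid a [grid_spec()].
#' @param folds a `cv_folds` list.
#' @param metric,threshold_cfg,seed,prob_folds as in [cross_validate()].
#' @param verbose print progress.
#' @return List with `best_params` ([hyper_params()]), `best_report`
#'   (the winning [cross_validate()] report), and `table` (data.frame C,
#'   gamma, threshold, metric_value, fold values).
#' @export
grid_search <- function(dataset, grid, folds,
                        metric = c("overall", "threshold"),
                        threshold_cfg = threshold_config(), seed = 1L,
                        prob_folds = 3L, verbose = FALSE) {
  metric <- match.arg(metric)
  pts <- grid_points(grid)
  reports <- vector("list", nrow(pts))
  for (g in seq_len(nrow(pts))) {
    reports[[g]] <- cross_validate(dataset,
                                   hyper_params(pts$C[g], pts$gamma[g]),
                                   folds, metric = metric,
                                   threshold_cfg = threshold_cfg,
                                   seed = seed, prob_folds = prob_folds)
    if (verbose)
      message(sprintf("grid %d/%d: C=%.3g gamma=%.3g -> %.4f", g,
                      nrow(pts), pts$C[g], pts$gamma[g],
                      reports[[g]]$mean))
  }
  vals <- vapply(reports, `[[`, 0.0, "mean")
  # ties: smallest C, then smallest gamma; pts is sorted that way
  best <- which(vals == max(vals))[1]
  fold_mat <- do.call(rbind, lapply(reports, `[[`, "fold_values"))
  colnames(fold_mat) <- sprintf("fold_%d", seq_along(folds))
  tab <- data.frame(C = pts$C, gamma = pts$gamma,
                    threshold = vapply(reports, function(r)
                      r$chosen_threshold %||% NA_real_, 0.0),
                    metric_value = vals, fold_mat)
  list(best_params = hyper_params(pts$C[best], pts$gamma[best]),
       best_report = reports[[best]], table = tab, metric = metric)
}

#' Persist a grid-search table as CSV
#'
#' @param search a [grid_search()] result.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_grid_table <- function(search, path) {
  utils::write.csv(search$table, path, row.names = FALSE)
  invisible(path)
}
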