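# The two accuracy metrics of animal behaviour recognition, and confusion
# matrices with class merging.
#
# Overall accuracy: fraction of windows whose argmax-probability class is
# the true class. Threshold accuracy: each window is recoded against a
# probability threshold tau — a correct identification with confidence
# >= tau is a true positive, below tau a false negative; an incorrect one
# with confidence >= tau is a false positive, below tau a true negative —
# and accuracy = (TP + TN) / (TP + TN + FP + FN). The "confidence" of a
# window is the probability of its predicted (argmax) class. Equality
# p == tau counts as above.

#' Overall accuracy
#'
#' @param predicted,truth equal-length non-empty label vectors.
#' @return Fraction correct, in `[0, 1]`.
#' @export
overall_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0)
    ethocv_stop("ethocv_validation_error",
                "predicted and truth must be equal-length and non-empty")
  mean(predicted == truth)
}

#' Threshold-rule confusion counts
#'
#' Tallies TP/TN/FP/FN under the probability-threshold recoding (see the
#' module description). The four counts partition the segments.
#'
#' @param proba probability matrix (rows = segments, columns = classes,
#'   column names = class labels).
#' @param predicted argmax predictions for the same rows.
#' @param truth true labels.
#' @param tau probability threshold in (0, 1).
#' @return Object of class `threshold_counts`: list TP, TN, FP, FN.
#' @export
threshold_counts <- function(proba, predicted, truth, tau) {
  if (!is_scalar_num(tau) || tau <= 0 || tau >= 1)
    ethocv_stop("ethocv_validation_error", "tau must be in (0, 1)")
  stopifnot(nrow(proba) == length(predicted),
            length(predicted) == length(truth))
  conf <- proba[cbind(seq_len(nrow(proba)),
                      match(predicted, colnames(proba)))]
  correct <- predicted == truth
  above <- conf >= tau
  structure(list(TP = sum(correct & above), FN = sum(correct & !above),
                 FP = sum(!correct & above), TN = sum(!correct & !above)),
            class = "threshold_counts")
}

#' Threshold accuracy from counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts a [threshold_counts()] result.
#' @return Fraction in `[0, 1]`.
#' @export
threshold_accuracy <- function(counts) {
  stopifnot(inherits(counts, "threshold_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0)
    ethocv_stop("ethocv_validation_error", "no segments to evaluate")
  (counts$TP + counts$TN) / total
}

#' Candidate probability thresholds
#'
#' @param thresholds strictly increasing values in (0, 1); default the
#'   published candidate set 0.5, 0.6, 0.7, 0.8, 0.9.
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  if (length(thresholds) == 0 || any(thresholds <= 0 | thresholds >= 1) ||
      is.unsorted(thresholds, strictly = TRUE))
    ethocv_stop("ethocv_validation_error",
                "thresholds must be strictly increasing values in (0, 1)")
  structure(list(thresholds = thresholds), class = "threshold_config")
}

#' Pick the threshold maximizing threshold accuracy
#'
#' Evaluates every candidate and returns the maximizer; ties go to the
#' smallest threshold. Note the degeneracy this metric invites: a model
#' that is always wrong but never confident turns every segment into a
#' true negative and attains threshold accuracy 1.
#'
#' @param proba,predicted,truth as in [threshold_counts()].
#' @param config a [threshold_config()].
#' @return List with `tau` (chosen threshold), `value` (its threshold
#'   accuracy) and `all` (data.frame of every candidate).
#' @export
choose_best_threshold <- function(proba, predicted, truth,
                                  config = threshold_config()) {
  vals <- vapply(config$thresholds, function(tau)
    threshold_accuracy(threshold_counts(proba, predicted, truth, tau)), 0.0)
  best <- which.max(vals)  # first maximum = smallest tau on ties
  list(tau = config$thresholds[best], value = vals[best],
       all = data.frame(tau = config$thresholds, value = vals))
}

#' Confusion counts and row-normalized confusion matrix
#'
#' @param predicted,truth label vectors.
#' @param classes class list defining row/column order (default: natural
#'   ethogram order restricted to observed classes).
#' @return `confusion_counts`: integer matrix of counts, rows = true
#'   class, columns = predicted class.
#' @export
confusion_counts <- function(predicted, truth, classes = NULL) {
  if (length(truth) == 0)
    ethocv_stop("ethocv_validation_error", "empty input")
  classes <- classes %||%
    {eo <- ethogram_classes()
     c(intersect(eo, union(truth, predicted)),
       sort(setdiff(union(truth, predicted), eo)))}
  bad <- setdiff(union(predicted, truth), classes)
  if (length(bad))
    ethocv_stop("ethocv_class_error", "label(s) outside the class list: %s",
                paste(unique(bad), collapse = ", "))
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  matrix(as.integer(tab), nrow = length(classes),
         dimnames = list(truth = classes, predicted = classes))
}

#' @rdname confusion_counts
#' @return `confusion_matrix`: the row-normalized matrix; entry (i, j) is
#'   the fraction of true-class-i segments predicted as class j. Rows
#'   without true examples are NA and flagged in the `empty_rows`
#'   attribute.
#' @export
confusion_matrix <- function(predicted, truth, classes = NULL) {
  normalize_confusion(confusion_counts(predicted, truth, classes))
}

# Row-normalize a count matrix, flagging empty rows.
normalize_confusion <- function(counts) {
  rs <- rowSums(counts)
  M <- counts / ifelse(rs == 0, NA_real_, rs)
  attr(M, "empty_rows") <- rownames(counts)[rs == 0]
  M
}

#' Merge behaviour classes in a confusion matrix
#'
#' Sums confusion counts over merged rows and columns before
#' row-normalizing — e.g. pooling lay/sit/stand into "passive" and
#' eat/drink into "feeding". The merge map must partition the class list.
#'
#' @param counts a [confusion_counts()] matrix.
#' @param merge_map named list: merged-class name -> character vector of
#'   original classes. Original classes not mentioned keep their name.
#' @return Row-normalized merged matrix (counts in attribute `counts`).
#' @export
merge_classes <- function(counts, merge_map) {
  classes <- rownames(counts)
  mentioned <- unlist(merge_map, use.names = FALSE)
  if (anyDuplicated(mentioned) || !all(mentioned %in% classes))
    ethocv_stop("ethocv_validation_error",
                "merge map must partition the class list (no duplicates, "
                %+% "all names known)")
  for (cls in setdiff(classes, mentioned)) merge_map[[cls]] <- cls
  # preserve original ordering: merged class sits where its first member was
  first_pos <- vapply(merge_map, function(v) min(match(v, classes)), 0)
  merge_map <- merge_map[order(first_pos)]
  merged <- matrix(0L, length(merge_map), length(merge_map),
                   dimnames = list(truth = names(merge_map),
                                   predicted = names(merge_map)))
  for (a in names(merge_map)) for (b in names(merge_map))
    merged[a, b] <- sum(counts[merge_map[[a]], merge_map[[b]], drop = FALSE])
  out <- normalize_confusion(merged)
  attr(out, "counts") <- merged
  out
}

`%+%` <- function(a, b) paste0(a, b)

#' The passive/feeding merge used in cross-group transfer analyses
#'
#' @return Named list pooling lay/sit/stand into `passive` and eat/drink
#'   into `feeding`; gaits stay separate.
#' @export
passive_feeding_merge <- function() {
  list(passive = PASSIVE_CLASSES, feeding = FEEDING_CLASSES)
}
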