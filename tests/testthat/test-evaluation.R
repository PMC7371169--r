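# A tiny builder for metric tests: a probability matrix over two classes
# with the given confidence for the predicted class of each segment.
proba_of <- function(pred, conf, classes = c("a", "b")) {
  P <- matrix(0, length(pred), length(classes),
              dimnames = list(NULL, classes))
  for (i in seq_along(pred)) {
    P[i, pred[i]] <- conf[i]
    P[i, setdiff(classes, pred[i])[1]] <- 1 - conf[i]
  }
  P
}

test_that("overall accuracy counts correct guesses", {
  expect_equal(overall_accuracy(rep("a", 10), rep("a", 10)), 1.0)
  expect_equal(overall_accuracy(rep("a", 4), rep("b", 4)), 0.0)
  expect_equal(overall_accuracy(c("a", "b", "b", "b"),
                                c("a", "a", "b", "b")), 0.75)
  expect_error(overall_accuracy(character(0), character(0)),
               class = "ethocv_validation_error")
  expect_error(overall_accuracy(c("a"), c("a", "b")),
               class = "ethocv_validation_error")
})

test_that("threshold recoding follows the four rules", {
  # correct & confident -> TP; incorrect & unconfident -> TN
  P <- proba_of(c("a", "a"), c(0.9, 0.3))
  tc <- threshold_counts(P, c("a", "a"), c("a", "b"), 0.5)
  expect_equal(tc$TP, 1)  # correct, p = 0.9 >= 0.5
  expect_equal(tc$TN, 1)  # incorrect, p = 0.3 < 0.5

  # the 8-segment worked example: 3 TP, 2 TN, 1 FP, 2 FN
  pred <- rep("a", 8)
  truth <- c("a", "a", "a", "b", "b", "b", "a", "a")
  conf <- c(0.9, 0.8, 0.7, 0.2, 0.3, 0.9, 0.4, 0.45)
  tc <- threshold_counts(proba_of(pred, conf), pred, truth, 0.5)
  expect_equal(unclass(tc)[c("TP", "TN", "FP", "FN")],
               list(TP = 3L, TN = 2L, FP = 1L, FN = 2L))
  expect_equal(threshold_accuracy(tc), 0.625)

  # boundary: p == tau counts as above
  tcb <- threshold_counts(proba_of("a", 0.5), "a", "a", 0.5)
  expect_equal(tcb$TP, 1)

  expect_error(threshold_counts(proba_of("a", 0.5), "a", "a", 1.5),
               class = "ethocv_validation_error")
})

test_that("threshold counts match a brute-force rule oracle", {
  # every (correct, above)-combination for small segment counts
  oracle <- function(correct, above) {
    list(TP = sum(correct & above), FN = sum(correct & !above),
         FP = sum(!correct & above), TN = sum(!correct & !above))
  }
  run_case <- function(correct, above, tau = 0.6) {
    n <- length(correct)
    conf <- ifelse(above, tau + 0.2, tau - 0.2)
    pred <- rep("a", n)
    truth <- ifelse(correct, "a", "b")
    got <- threshold_counts(proba_of(pred, conf), pred, truth, tau)
    expect_equal(unclass(got)[c("TP", "FN", "FP", "TN")],
                 oracle(correct, above))
  }
  for (n in 1:4)  # exhaustive over the 4^n rule combinations
    for (code in 0:(4^n - 1)) {
      digits <- (code %/% 4^(0:(n - 1))) %% 4
      run_case(correct = digits %/% 2 == 1, above = digits %% 2 == 1)
    }
  set.seed(42)  # random cases up to 12 segments
  for (rep in 1:200) {
    n <- sample(5:12, 1)
    run_case(correct = runif(n) < 0.5, above = runif(n) < 0.5)
  }
})

test_that("metric identities hold exactly", {
  set.seed(7)
  n <- 40
  pred <- sample(c("a", "b"), n, replace = TRUE)
  truth <- sample(c("a", "b"), n, replace = TRUE)

  # all confidences >= tau: threshold accuracy == overall accuracy
  P_hi <- proba_of(pred, runif(n, 0.9, 1))
  expect_identical(
    threshold_accuracy(threshold_counts(P_hi, pred, truth, 0.6)),
    overall_accuracy(pred, truth))

  # all confidences < tau: threshold accuracy == 1 - overall accuracy
  P_lo <- proba_of(pred, runif(n, 0.51, 0.58))
  expect_identical(
    threshold_accuracy(threshold_counts(P_lo, pred, truth, 0.6)),
    1 - overall_accuracy(pred, truth))

  # tau <= 1/K forces equality with overall accuracy (row maxima >= 1/K)
  K <- 8
  Pk <- matrix(runif(n * K), n, K,
               dimnames = list(NULL, letters[1:K]))
  Pk <- Pk / rowSums(Pk)
  predk <- letters[1:K][max.col(Pk, ties.method = "first")]
  truthk <- sample(letters[1:K], n, replace = TRUE)
  expect_identical(
    threshold_accuracy(threshold_counts(Pk, predk, truthk, 1 / K)),
    overall_accuracy(predk, truthk))
})

test_that("threshold choice maximizes, with the degenerate optimum exposed", {
  cfg <- threshold_config()
  # always wrong, never confident: every segment becomes a true negative
  # at every candidate -> value 1 at tau = 0.5 (smallest on ties)
  n <- 20
  pred <- rep("a", n); truth <- rep("b", n)
  P <- proba_of(pred, rep(0.4, n))
  best <- choose_best_threshold(P, pred, truth, cfg)
  expect_equal(best$tau, 0.5)
  expect_equal(best$value, 1.0)
  expect_equal(overall_accuracy(pred, truth), 0.0)

  # perfectly confident and correct: 1.0 everywhere, tie -> 0.5
  P2 <- proba_of(truth, rep(0.99, n))
  best2 <- choose_best_threshold(P2, truth, truth, cfg)
  expect_equal(best2$tau, 0.5)
  expect_equal(best2$value, 1.0)

  best3 <- choose_best_threshold(P, pred, truth, threshold_config(0.7))
  expect_equal(best3$tau, 0.7)

  expect_error(threshold_config(c(0.5, 0.5)),
               class = "ethocv_validation_error")
})

test_that("confusion matrices tally, normalize and merge correctly", {
  M <- confusion_matrix(c("a", "b", "b", "b"), c("a", "a", "b", "b"),
                        classes = c("a", "b"))
  expect_equal(unname(M), rbind(c(0.5, 0.5), c(0, 1)), ignore_attr = TRUE)

  perfect <- confusion_matrix(rep(letters[1:3], 5), rep(letters[1:3], 5),
                              classes = letters[1:3])
  expect_equal(unname(perfect), diag(3), ignore_attr = TRUE)

  set.seed(3)
  pred <- sample(letters[1:4], 60, replace = TRUE)
  truth <- sample(letters[1:4], 60, replace = TRUE)
  M2 <- confusion_matrix(pred, truth, classes = letters[1:4])
  expect_equal(unname(rowSums(M2)), rep(1, 4), tolerance = 1e-9)

  expect_error(confusion_counts("z", "a", classes = c("a", "b")),
               class = "ethocv_class_error")

  cc <- confusion_counts(pred, truth, classes = letters[1:4])
  ident <- merge_classes(cc, list(a = "a", b = "b", c = "c", d = "d"))
  expect_equal(attr(ident, "counts"), cc, ignore_attr = TRUE)
  all1 <- merge_classes(cc, list(all = letters[1:4]))
  expect_equal(dim(all1), c(1, 1))
  expect_equal(all1[1, 1], 1.0)
  expect_error(merge_classes(cc, list(x = c("a", "b"), y = c("b", "c"))),
               class = "ethocv_validation_error")
})

test_that("merging can only grow total diagonal mass (brute force)", {
  set.seed(9)
  for (r in 1:50) {
    counts <- matrix(rpois(36, 5), 6, 6,
                     dimnames = list(truth = letters[1:6],
                                     predicted = letters[1:6]))
    map <- split(letters[1:6], sample(1:3, 6, replace = TRUE))
    names(map) <- paste0("m", seq_along(map))
    merged <- merge_classes(counts, map)
    mc <- attr(merged, "counts")
    expect_gte(sum(diag(mc)), sum(diag(counts)))
  }
})

test_that("per-individual folds partition by animal", {
  ds <- test_dataset(n_ind = 3, dur = 5, lambda = 0.4, seed = 6)
  folds <- make_individual_folds(ds)
  expect_length(folds, 3)
  test_idx <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_idx, seq_along(ds$labels))  # cover, disjoint
  for (f in folds) {
    expect_length(intersect(ds$individual_id[f$train],
                            ds$individual_id[f$test]), 0)
    expect_length(unique(ds$individual_id[f$test]), 1)
  }
  one <- subset_rows(ds, ds$individual_id == ds$individual_id[1])
  expect_error(make_individual_folds(one),
               class = "ethocv_validation_error")
})

test_that("random folds respect fraction, k-fold partitioning and seed", {
  ds <- cluster_dataset(n_per = 500, classes = c("a", "b"))  # n = 1000
  f1 <- make_random_folds(ds, cv_config("random", 0.3, 7, "split", seed = 5))
  expect_length(f1, 7)
  expect_true(all(vapply(f1, function(f) length(f$test), 0L) == 300))

  ds7 <- cluster_dataset(n_per = 350, classes = c("a", "b"))  # n = 700
  fk <- make_random_folds(ds7, cv_config("random", n_repeats = 7,
                                         mode = "kfold", seed = 5))
  expect_true(all(vapply(fk, function(f) length(f$test), 0L) == 100))
  expect_equal(sort(unlist(lapply(fk, `[[`, "test"))), 1:700)

  f2 <- make_random_folds(ds, cv_config("random", 0.3, 7, "split", seed = 5))
  expect_identical(f1, f2)
  expect_error(cv_config("random", test_fraction = 0),
               class = "ethocv_validation_error")
})

test_that("cross_validate reports means, CIs and confusion coherently", {
  ds <- cluster_dataset(n_per = 30, classes = c("a", "b", "c"), sep = 8,
                        n_ind = 3)
  folds <- make_individual_folds(ds)
  rep <- cross_validate(ds, hyper_params(10, 0.1), folds)
  expect_gt(rep$mean, 0.95)  # separable construction
  expect_equal(rep$mean, mean(rep$fold_values))
  expect_true(all(rep$fold_values >= 0 & rep$fold_values <= 1))
  expect_equal(rep$chance_level, 1 / 3)
  expect_equal(unname(rowSums(rep$confusion)), rep(1, 3), tolerance = 1e-9)

  # fold whose training side is single-class -> named error
  bad <- ds
  bad$labels[bad$individual_id != "ind1"] <- "a"
  expect_error(cross_validate(bad, hyper_params(10, 0.1),
                              make_individual_folds(bad)),
               class = "ethocv_single_class_error")
})

test_that("grid search evaluates every point and reports the maximum", {
  ds <- cluster_dataset(n_per = 25, classes = c("a", "b"), sep = 4,
                        n_ind = 2)
  folds <- make_individual_folds(ds)
  gs <- grid_search(ds, grid_spec(C_min = 1, C_max = 100, C_n = 2,
                                  gamma_min = 0.01, gamma_max = 1,
                                  gamma_n = 3),
                    folds, metric = "overall")
  expect_equal(nrow(gs$table), 6)
  expect_equal(gs$best_report$mean, max(gs$table$metric_value))
  # tie rule: the winner is the first (smallest C, then gamma) maximizer
  winners <- which(gs$table$metric_value == max(gs$table$metric_value))
  expect_equal(gs$best_params$C, gs$table$C[winners[1]])
  expect_equal(gs$best_params$gamma, gs$table$gamma[winners[1]])

  p <- withr::local_tempfile(fileext = ".csv")
  write_grid_table(gs, p)
  expect_equal(nrow(read.csv(p)), 6)
})
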