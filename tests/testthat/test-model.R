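test_that("hyperparameters and grid spec validate; grid enumerates", {
  expect_error(hyper_params(0, 1), class = "ethocv_validation_error")
  expect_error(hyper_params(1, -1), class = "ethocv_validation_error")
  pts <- grid_points(grid_spec(C_min = 1, C_max = 100, C_n = 2,
                               gamma_min = 0.1, gamma_max = 10, gamma_n = 3))
  expect_equal(nrow(pts), 6)
  expect_equal(sort(unique(pts$C)), c(1, 100))
  # even log spacing
  expect_equal(diff(log10(sort(unique(pts$gamma)))), c(1, 1))
})

test_that("binary decision values match the reference SVM implementation", {
  # frozen oracle: decision_function values computed with a reference
  # RBF-SVM implementation (tol 1e-6) on this exact fixture
  X <- matrix(c(1.6905, -0.4659, 0.0328, 0.4075, -0.7889, 0.0021, -0.0009,
                -1.7547, 1.0177, 0.6005, -0.6254, -0.1715, 0.5053, -0.2614,
                -0.2427, -1.4532, 0.5546, 0.1239, 0.2745, -1.5265, 1.6507,
                0.1543, -0.3871, 2.0291, -0.0454, -1.4507, -0.4052, -2.2883,
                1.0494, -0.4165, 0.8574, 2.6725, -0.0511, 2.1354, -0.4644,
                0.9378, 0.3958, 3.062, 3.3662, 1.2706, 2.4407, 1.42, 2.1681,
                0.8472, -0.1083, -0.2031, 1.9831, 3.8476, 1.8694, 1.0754,
                3.512, 1.8373, 1.7014, 1.8526, 1.4676, 1.2905, 0.165, 2.1016,
                1.5052, 2.7931), 20, 3, byrow = TRUE)
  Xt <- matrix(c(0.3574, -1.4876, 0.6805, 2.8394, 0.3399, -0.2678, -0.6323,
                 -0.46, 0.4398, -0.616, 2.5972, 0.4608, 0.9304, 2.5259,
                 2.604, 0.5447, 1.1984, 1.682), 6, 3, byrow = TRUE)
  y <- rep(c(1, -1), each = 10)
  oracle <- list(
    "1_0.5"  = c(1.125028, -0.687423, 0.959102, -0.290566, -0.964845,
                 -0.325959),
    "50_0.1" = c(2.476637, -0.955934, 2.680228, -0.44144, -1.899277,
                 -0.819349))
  for (key in names(oracle)) {
    cg <- as.numeric(strsplit(key, "_")[[1]])
    fit <- ethocv:::.smo_solve(X, y, cg[1], cg[2], 1e-5, 1000000L)
    kc <- ethocv:::.rbf_cross_kernel(X, Xt, cg[2])
    dec <- as.vector(crossprod(kc, fit$alpha * y)) + fit$b
    expect_equal(dec, oracle[[key]], tolerance = 1e-3)
  }
})

test_that("separable clusters are fit perfectly and deterministically", {
  ds <- cluster_dataset(n_per = 15, classes = c("a", "b", "c"))
  m <- svm_fit(ds, hyper_params(10, 0.1), seed = 3)
  expect_identical(m$classes, c("a", "b", "c"))  # lexicographic
  expect_equal(predict(m, ds), ds$labels)

  m2 <- svm_fit(ds, hyper_params(10, 0.1), seed = 3)
  expect_identical(predict_proba(m, ds), predict_proba(m2, ds))

  expect_error(svm_fit(subset_rows(ds, ds$labels == "a"),
                       hyper_params(10, 0.1)),
               class = "ethocv_single_class_error")
})

test_that("probability matrix is a proper distribution over trained classes", {
  ds <- cluster_dataset(n_per = 12, classes = c("a", "b", "c", "d"), sep = 3)
  m <- svm_fit(ds, hyper_params(10, 0.1), seed = 5)
  P <- predict_proba(m, ds)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(apply(P, 1, max) >= 1 / ncol(P)))  # pigeonhole
  expect_identical(colnames(P), c("a", "b", "c", "d"))

  # a class absent from training has no probability column, never appears
  sub <- subset_rows(ds, ds$labels != "d")
  m3 <- svm_fit(sub, hyper_params(10, 0.1), seed = 5)
  P3 <- predict_proba(m3, ds)
  expect_identical(colnames(P3), c("a", "b", "c"))
  expect_false("d" %in% predict(m3, ds))

  # zero test rows: empty matrix, no error
  P0 <- predict_proba(m, subset_rows(ds, integer(0)))
  expect_equal(nrow(P0), 0)

  # feature-name mismatch is rejected
  bad <- ds; colnames(bad$features)[1] <- "zz"; bad$feature_names[1] <- "zz"
  expect_error(predict_proba(m, bad), class = "ethocv_feature_error")
})

test_that("hard predictions are the probability argmax with first-class ties", {
  # direct argmax rule checks
  classes <- c("drink", "eat", "lay")
  P <- rbind(c(0.7, 0.2, 0.1), c(0.25, 0.5, 0.25), c(0.5, 0.5, 0))
  expect_identical(ethocv:::proba_argmax(P, classes),
                   c("drink", "eat", "drink"))

  # brute-force oracle on random probability rows
  set.seed(11)
  P <- matrix(runif(1000 * 4), 1000, 4)
  P <- P / rowSums(P)
  got <- ethocv:::proba_argmax(P, letters[1:4])
  want <- apply(P, 1, function(r) letters[1:4][which.max(r)])
  expect_identical(got, want)

  # model-level agreement between predict() and predict_proba()
  ds <- test_dataset(n_ind = 2, dur = 5, lambda = 0.4, seed = 6)
  m <- svm_fit(ds, default_test_params(), seed = 2)
  P <- predict_proba(m, ds)
  expect_identical(predict(m, ds), ethocv:::proba_argmax(P, m$classes))
})

test_that("model serialization round-trips predictions", {
  ds <- cluster_dataset(n_per = 10, classes = c("a", "b", "c"))
  m <- svm_fit(ds, hyper_params(10, 0.1), seed = 3)
  p <- withr::local_tempfile(fileext = ".json")
  save_model(m, p)
  m2 <- load_model(p)
  expect_equal(predict_proba(m2, ds), predict_proba(m, ds),
               tolerance = 1e-9)
  expect_identical(predict(m2, ds), predict(m, ds))
})
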