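# Multi-class probabilistic classification: a soft-margin RBF-kernel SVM
# trained one-versus-one, with per-pair Platt sigmoid calibration (fitted
# on internally cross-validated decision values) and pairwise coupling of
# the K*(K-1)/2 pairwise probabilities into a K-class probability vector.
# The dual problems are solved by the compiled SMO routine in src/.

#' Hyperparameters of the RBF-kernel SVM
#'
#' @param C margin penalty, > 0.
#' @param gamma RBF kernel width, > 0; `k(x, z) = exp(-gamma * |x - z|^2)`.
#' @return Object of class `hyper_params`.
#' @export
hyper_params <- function(C, gamma) {
  if (!is_scalar_num(C) || C <= 0 || !is_scalar_num(gamma) || gamma <= 0)
    ethocv_stop("ethocv_validation_error", "C and gamma must both be > 0")
  structure(list(C = C, gamma = gamma), class = "hyper_params")
}

#' Log-spaced hyperparameter grid
#'
#' Defaults reproduce the full published search space: 27 points between
#' 1e-5 and 1e9 for C and 24 points between 1e-9 and 1e3 for gamma, evenly
#' spaced on a logarithmic scale — 648 pairs. Desk-scale experiments use a
#' reduced grid over the same ranges (see [experiment_config()]).
#'
#' @param C_min,C_max,C_n C range endpoints and point count.
#' @param gamma_min,gamma_max,gamma_n gamma range endpoints and count.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(C_min = 1e-5, C_max = 1e9, C_n = 27,
                      gamma_min = 1e-9, gamma_max = 1e3, gamma_n = 24) {
  stopifnot(C_min > 0, C_max >= C_min, C_n >= 1,
            gamma_min > 0, gamma_max >= gamma_min, gamma_n >= 1)
  structure(list(C_min = C_min, C_max = C_max, C_n = as.integer(C_n),
                 gamma_min = gamma_min, gamma_max = gamma_max,
                 gamma_n = as.integer(gamma_n)),
            class = "grid_spec")
}

logspace <- function(lo, hi, n)
  if (n == 1) lo else 10^seq(log10(lo), log10(hi), length.out = n)

#' Enumerate the grid points of a [grid_spec()]
#'
#' @param spec a `grid_spec`.
#' @return Data.frame with columns `C` and `gamma`, C varying slowest.
#' @export
grid_points <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  expand.grid(gamma = logspace(spec$gamma_min, spec$gamma_max, spec$gamma_n),
              C = logspace(spec$C_min, spec$C_max, spec$C_n),
              KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
}

# Platt sigmoid fit: minimize the calibrated cross-entropy of
# p = 1 / (1 + exp(A*f + B)) over (A, B), by Newton's method with
# backtracking (the numerically stable formulation).
platt_fit <- function(dec, y, max_iter = 100, min_step = 1e-10, sigma = 1e-12) {
  prior1 <- sum(y > 0); prior0 <- sum(y <= 0)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    fApB <- dec * A + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- dec * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dec * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(dec * dec * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(dec * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      newf <- fval(A + step * dA, B + step * dB)
      if (newf < fv + 1e-4 * step * gd) {
        A <- A + step * dA; B <- B + step * dB; fv <- newf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  list(A = A, B = B)
}

# Couple pairwise probabilities r[i,j] = P(class i | class i or j, x) into
# a K-vector (second method of the standard pairwise-coupling paper; the
# construction the one-versus-one implementation the field uses is based
# on). Fixed-point iteration on the KKT system of the quadratic program.
pairwise_couple <- function(R, max_iter = 100, eps = 1e-12) {
  K <- nrow(R)
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) {
    Q[i, i] <- sum(R[-i, i]^2)
    for (j in seq_len(K)) if (j != i) Q[i, j] <- -R[j, i] * R[i, j]
  }
  p <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    Qp <- as.vector(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < eps * K) break
    for (t in seq_len(K)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p
}

#' Fit the one-versus-one probabilistic RBF-SVM
#'
#' Trains one binary soft-margin SVM per unordered class pair and a Platt
#' sigmoid per pair. Calibration decision values come from an internal
#' `prob_folds`-fold cross-validation whose fold assignment is fixed by
#' `seed`, so the fit is deterministic given (data, params, seed).
#'
#' @param train a `feature_dataset` with >= 2 classes present.
#' @param params a [hyper_params()].
#' @param seed integer seed (calibration fold assignment only; the SMO
#'   solver itself is deterministic).
#' @param standardize fit a feature standardizer on the training rows and
#'   store it in the model (default TRUE).
#' @param prob_folds internal calibration folds (default 3); pairs with
#'   fewer than 3 examples of either class are calibrated on training
#'   decision values instead.
#' @param eps SMO stopping tolerance.
#' @param max_iter SMO iteration cap per binary problem.
#' @return Object of class `ethocv_svm` with the lexicographically sorted
#'   class list, per-pair support vectors/coefficients/sigmoids, and the
#'   standardization parameters.
#' @export
svm_fit <- function(train, params, seed = 1L, standardize = TRUE,
                    prob_folds = 3L, eps = 1e-3, max_iter = 1000000L) {
  stopifnot(inherits(train, "feature_dataset"),
            inherits(params, "hyper_params"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2)
    ethocv_stop("ethocv_single_class_error",
                "training data has a single class ('%s')", classes)
  scaler <- if (standardize) standardizer_fit(train$features)
            else list(center = rep(0, ncol(train$features)),
                      scale = rep(1, ncol(train$features)))
  X <- standardizer_apply(train$features, scaler)
  K <- length(classes)
  pairs <- list()
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    sel <- train$labels %in% c(classes[i], classes[j])
    Xp <- X[sel, , drop = FALSE]
    yp <- ifelse(train$labels[sel] == classes[i], 1, -1)
    fit <- .smo_solve(Xp, yp, params$C, params$gamma, eps, max_iter)
    keep <- fit$alpha > 1e-12
    pair_seed <- derive_seed(seed, i * K + j)

    # calibration decision values: internal CV when both classes allow it
    n1 <- sum(yp > 0); n0 <- sum(yp < 0)
    if (min(n1, n0) >= 3 && prob_folds >= 2) {
      nf <- min(prob_folds, n1, n0)
      fold <- integer(length(yp))
      with_seed(pair_seed, {
        fold[yp > 0] <- sample(rep_len(seq_len(nf), n1))
        fold[yp < 0] <- sample(rep_len(seq_len(nf), n0))
      })
      dec <- numeric(length(yp))
      for (f in seq_len(nf)) {
        tr <- fold != f
        sub <- .smo_solve(Xp[tr, , drop = FALSE], yp[tr], params$C,
                          params$gamma, eps, max_iter)
        kc <- .rbf_cross_kernel(Xp[tr, , drop = FALSE],
                                Xp[!tr, , drop = FALSE], params$gamma)
        dec[!tr] <- as.vector(crossprod(kc, sub$alpha * yp[tr])) + sub$b
      }
    } else {
      kc <- .rbf_cross_kernel(Xp[keep, , drop = FALSE], Xp, params$gamma)
      dec <- as.vector(crossprod(kc, (fit$alpha * yp)[keep])) + fit$b
    }
    sig <- platt_fit(dec, yp)
    pairs[[length(pairs) + 1]] <-
      list(i = i, j = j, sv = Xp[keep, , drop = FALSE],
           coef = (fit$alpha * yp)[keep], b = fit$b, A = sig$A, B = sig$B)
  }
  structure(list(classes = classes, pairs = pairs, params = params,
                 scaler = scaler, feature_names = train$feature_names,
                 seed = seed, version = "1"),
            class = "ethocv_svm")
}

# Decision values of one trained pair on pre-standardized rows.
pair_decision <- function(pair, X, gamma) {
  if (nrow(pair$sv) == 0) return(rep(pair$b, nrow(X)))
  kc <- .rbf_cross_kernel(pair$sv, X, gamma)
  as.vector(crossprod(kc, pair$coef)) + pair$b
}

#' Class-probability predictions
#'
#' Pairwise sigmoid probabilities are coupled into a probability vector per
#' row; rows sum to 1, columns follow the model's sorted class list.
#'
#' @param model an `ethocv_svm`.
#' @param test a `feature_dataset` (or bare feature matrix) whose feature
#'   names match the training features.
#' @return Numeric matrix, rows = test rows, columns = model classes.
#' @export
predict_proba <- function(model, test) {
  stopifnot(inherits(model, "ethocv_svm"))
  feats <- if (inherits(test, "feature_dataset")) test$features else test
  if (!identical(colnames(feats), model$feature_names))
    ethocv_stop("ethocv_feature_error",
                "test feature names do not match the training features")
  K <- length(model$classes)
  n <- nrow(feats)
  P <- matrix(NA_real_, n, K, dimnames = list(NULL, model$classes))
  if (n == 0) return(P)
  X <- standardizer_apply(feats, model$scaler)
  # r[[k]]: P(class i | i or j) for pair k, all rows at once
  rvals <- lapply(model$pairs, function(pr) {
    dec <- pair_decision(pr, X, model$params$gamma)
    p <- 1 / (1 + exp(pr$A * dec + pr$B))
    pmin(pmax(p, 1e-7), 1 - 1e-7)
  })
  R <- matrix(0, K, K)
  for (row in seq_len(n)) {
    for (k in seq_along(model$pairs)) {
      pr <- model$pairs[[k]]
      R[pr$i, pr$j] <- rvals[[k]][row]
      R[pr$j, pr$i] <- 1 - rvals[[k]][row]
    }
    P[row, ] <- if (K == 2) c(R[1, 2], R[2, 1]) else pairwise_couple(R)
  }
  P
}

#' Hard class predictions
#'
#' Row-wise argmax of [predict_proba()]; exact ties go to the earlier
#' class in the sorted class list.
#'
#' @param object an `ethocv_svm`.
#' @param newdata a `feature_dataset` or feature matrix.
#' @param ... unused.
#' @return Character vector of predicted classes.
#' @export
predict.ethocv_svm <- function(object, newdata, ...) {
  P <- predict_proba(object, newdata)
  proba_argmax(P, object$classes)
}

# Shared argmax-with-tie rule: first (earlier sorted class) maximum wins.
proba_argmax <- function(P, classes) {
  if (nrow(P) == 0) return(character(0))
  classes[max.col(P, ties.method = "first")]
}

#' Save / load a trained model
#'
#' Single-file JSON serialization (format version "1"): class list,
#' hyperparameters, standardizer, and per-pair support vectors,
#' coefficients, intercept and sigmoid.
#'
#' @param model an `ethocv_svm`.
#' @param path file path.
#' @return `save_model`: the path invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ethocv_svm"))
  out <- unclass(model)
  out$params <- unclass(out$params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.character(raw$version), "1"))
    ethocv_stop("ethocv_validation_error", "unknown model format version")
  fn <- unlist(raw$feature_names)
  pairs <- lapply(raw$pairs, function(pr) {
    sv <- do.call(rbind, lapply(pr$sv, unlist))
    if (is.null(sv)) sv <- matrix(0, 0, length(fn))
    colnames(sv) <- fn
    list(i = pr$i, j = pr$j, sv = sv, coef = as.double(unlist(pr$coef)),
         b = pr$b, A = pr$A, B = pr$B)
  })
  scaler <- list(center = unlist(raw$scaler$center),
                 scale = unlist(raw$scaler$scale))
  structure(list(classes = unlist(raw$classes), pairs = pairs,
                 params = hyper_params(raw$params$C, raw$params$gamma),
                 scaler = scaler, feature_names = fn,
                 seed = raw$seed, version = "1"),
            class = "ethocv_svm")
}
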