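# Shared fixtures, built in code and cached per test run. Datasets are
# deliberately small: short scripted intervals keep the SVM fits fast while
# leaving every behaviour with enough windows to be learnable.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A featurized single-group cohort.
test_dataset <- function(n_ind = 3, dur = 8, lambda = 0.5, seed = 7,
                         group = group_profile("test", 1),
                         behaviours = ethogram_classes()) {
  key <- paste("ds", n_ind, dur, lambda, seed, group$group_id,
               paste(behaviours, collapse = "."), sep = "_")
  cached(key, {
    script <- ethogram_script(behaviours, rep(dur, length(behaviours)))
    coh <- generate_cohort(n_ind, group, script, lambda, seed)
    build_feature_dataset(dataset_windows(coh))
  })
}

test_cohort <- function(n_ind = 3, dur = 8, lambda = 0.5, seed = 7,
                        group = group_profile("test", 1)) {
  key <- paste("coh", n_ind, dur, lambda, seed, group$group_id, sep = "_")
  cached(key, generate_cohort(n_ind, group, default_script(dur), lambda,
                              seed))
}

# A tiny hand-built feature dataset of two well-separated Gaussian
# clusters (optionally more classes on a simplex), for classifier tests
# that should not pay for signal synthesis.
cluster_dataset <- function(n_per = 20, classes = c("a", "b"), sep = 6,
                            d = 3, seed = 42, n_ind = 2) {
  set.seed(seed)
  centers <- diag(sep, length(classes), d)
  feats <- do.call(rbind, lapply(seq_along(classes), function(k)
    sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[k, ], `+`)))
  colnames(feats) <- paste0("f", seq_len(d))
  structure(list(features = feats,
                 labels = rep(classes, each = n_per),
                 individual_id = rep_len(sprintf("ind%d", seq_len(n_ind)),
                                         n_per * length(classes)),
                 group_id = rep("g", n_per * length(classes)),
                 feature_names = colnames(feats)),
            class = "feature_dataset")
}

default_test_params <- function() hyper_params(100, 0.05)
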