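#' @useDynLib ethocv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor fft median qnorm qt quantile rbinom
#' @importFrom utils read.csv write.csv modifyList
NULL

# Classed errors so callers and tests can distinguish failure modes.
ethocv_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "ethocv_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Derive a child seed from a master seed
#'
#' Hierarchical seeding: every stochastic stage of a pipeline draws its own
#' seed from the master seed and a stream index, so that e.g. adding an
#' individual to a cohort does not perturb the noise stream of another.
#' Results stay inside the 32-bit integer range `set.seed()` accepts.
#'
#' @param seed master seed (single integer).
#' @param ... one or more non-negative integer stream indices.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  m <- 2147483629  # largest prime below 2^31
  x <- as.double(seed %% m)
  for (k in as.double(idx)) {
    # 16-bit multiplier keeps the product exactly representable in a double
    x <- (x * 48271 + k + 1) %% m
  }
  as.integer(x)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
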