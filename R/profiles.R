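# Group- and individual-level variation: body-size classes shift gait
# frequency and amplitude; the individual effect lambda controls how far a
# single animal's signal signature deviates from its group baseline. This
# within-individual correlation is what makes random train/test splitting
# optimistic.

#' Group profile
#'
#' A body-size class of animals. `size_scale` shifts gait frequency down and
#' oscillation amplitude up with body size (large animals move their collars
#' further but cycle slower); `run_frequency_shift` adds a group-specific
#' offset (Hz) to the run gait only, so one group's run can resemble
#' another's trot.
#'
#' @param group_id character label.
#' @param size_scale positive scalar, 1 = reference size.
#' @param run_frequency_shift additive shift (Hz) applied to run.
#' @return Object of class `group_profile`.
#' @export
group_profile <- function(group_id, size_scale = 1, run_frequency_shift = 0) {
  stopifnot(is.character(group_id), length(group_id) == 1,
            is_scalar_num(run_frequency_shift))
  if (!is_scalar_num(size_scale) || size_scale <= 0)
    ethocv_stop("ethocv_validation_error", "size_scale must be > 0")
  structure(list(group_id = group_id, size_scale = size_scale,
                 run_frequency_shift = run_frequency_shift),
            class = "group_profile")
}

#' Sample an individual's signal signature
#'
#' Draws one animal's deviation from its group baseline: log-normal
#' multipliers on gait frequency and amplitude, and normal collar-attitude
#' offsets (roll/pitch/yaw, radians). The log-scale spreads are proportional
#' to the individual effect `individual_effect` (lambda); lambda = 0 yields
#' exchangeable individuals (multipliers exactly 1, offsets exactly 0).
#'
#' @param group a [group_profile()].
#' @param individual_effect lambda >= 0; spread scale of the signature.
#' @param seed integer seed; the draw is deterministic given
#'   (group, lambda, seed).
#' @param individual_id optional id; defaults to a seed-derived label.
#' @param freq_sigma,amp_sigma,orient_sigma spread per unit lambda:
#'   log-sd of the frequency and amplitude multipliers and sd (rad) of the
#'   attitude offsets.
#' @return Object of class `individual_profile`.
#' @export
sample_individual_profile <- function(group, individual_effect, seed,
                                      individual_id = NULL,
                                      freq_sigma = 0.25, amp_sigma = 0.35,
                                      orient_sigma = 0.60) {
  stopifnot(inherits(group, "group_profile"))
  if (!is_scalar_num(individual_effect) || individual_effect < 0)
    ethocv_stop("ethocv_validation_error",
                "individual_effect (lambda) must be >= 0")
  lam <- individual_effect
  if (lam == 0) {
    fm <- 1; am <- 1; off <- c(0, 0, 0)
  } else {
    draws <- with_seed(seed, rnorm(5))
    fm <- exp(freq_sigma * lam * draws[1])
    am <- exp(amp_sigma * lam * draws[2])
    off <- orient_sigma * lam * draws[3:5]
  }
  structure(list(
    individual_id = individual_id %||% sprintf("%s_ind%d", group$group_id,
                                               seed %% 10000L),
    group_id = group$group_id,
    freq_multiplier = fm, amplitude_multiplier = am,
    orientation_offset = off, individual_effect = lam),
    class = "individual_profile")
}
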