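# Synthesis of one individual's 9-channel collar stream from a scripted
# behaviour sequence. Channels: tri-axial acceleration (g), tri-axial
# angular rate (rad/s), attitude as roll/pitch/yaw Euler angles (rad),
# sampled at a fixed rate (default 50 Hz).

#' Scripted behaviour sequence
#'
#' @param behaviours character vector of ethogram classes.
#' @param durations matching vector of durations in seconds (> 0).
#' @return Object of class `ethogram_script` (data.frame behaviour/duration).
#' @export
ethogram_script <- function(behaviours, durations) {
  stopifnot(length(behaviours) == length(durations), length(behaviours) >= 1)
  bad <- setdiff(behaviours, ethogram_classes())
  if (length(bad))
    ethocv_stop("ethocv_class_error", "unknown behaviour(s): %s",
                paste(unique(bad), collapse = ", "))
  if (!all(durations > 0))
    ethocv_stop("ethocv_validation_error", "all durations must be > 0")
  structure(data.frame(behaviour = as.character(behaviours),
                       duration = as.double(durations),
                       stringsAsFactors = FALSE),
            class = c("ethogram_script", "data.frame"))
}

#' One interval of every behaviour, in ethogram order
#'
#' @param duration_each seconds per behaviour (default 20, recycled).
#' @return An [ethogram_script()].
#' @export
default_script <- function(duration_each = 20) {
  ethogram_script(ethogram_classes(),
                  rep_len(duration_each, 8))
}

#' Recording metadata
#'
#' @param individual_id,group_id identifiers carried through the pipeline.
#' @param sampling_rate Hz, > 0 (default 50, the collar logger's rate).
#' @return Object of class `recording_meta`.
#' @export
recording_meta <- function(individual_id, group_id, sampling_rate = 50) {
  if (!is_scalar_num(sampling_rate) || sampling_rate <= 0)
    ethocv_stop("ethocv_validation_error", "sampling_rate must be > 0")
  structure(list(individual_id = individual_id, group_id = group_id,
                 sampling_rate = sampling_rate, channels = CHANNELS9),
            class = "recording_meta")
}

# Intrinsic rotation by roll (x), pitch (y), yaw (z) Euler angles.
euler_rotation <- function(ang) {
  cr <- cos(ang[1]); sr <- sin(ang[1])
  cp <- cos(ang[2]); sp <- sin(ang[2])
  cy <- cos(ang[3]); sy <- sin(ang[3])
  Rx <- rbind(c(1, 0, 0), c(0, cr, -sr), c(0, sr, cr))
  Ry <- rbind(c(cp, 0, sp), c(0, 1, 0), c(-sp, 0, cp))
  Rz <- rbind(c(cy, -sy, 0), c(sy, cy, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Generate one labelled recording
#'
#' Synthesizes the 9-channel stream for a scripted behaviour sequence. Per
#' behaviour interval, acceleration is the (attitude-rotated) gravity
#' baseline plus a per-axis sinusoid at the profile- and group-scaled
#' fundamental frequency plus Gaussian noise; angular rate is the analogous
#' oscillation without the gravity term; attitude is the slowly varying
#' orientation angles plus noise. Feeding behaviours additionally receive
#' short decaying bursts at the model's `burstiness` rate.
#'
#' The effective frequency is `osc_frequency * freq_multiplier / size_scale`
#' (plus `run_frequency_shift` for run); the effective acceleration
#' amplitude is `osc_amplitude * amplitude_multiplier * size_scale` times
#' the squared ratio of the effective to the group-baseline frequency, so
#' frequency deviations carry their physical amplitude consequence.
#'
#' @param profile an [sample_individual_profile()] result.
#' @param group the individual's [group_profile()].
#' @param script an [ethogram_script()].
#' @param meta a [recording_meta()].
#' @param seed integer seed for the noise stream.
#' @param models behaviour models, default [default_behaviour_models()].
#' @return List with elements `recording` (data.frame `t` plus the 9
#'   channels, class `inertial_recording`, metadata in attributes) and
#'   `labels` (data.frame `start_s`/`end_s`/`behaviour`, half-open
#'   intervals, class `label_track`).
#' @export
generate_recording <- function(profile, group, script, meta, seed,
                               models = default_behaviour_models()) {
  stopifnot(inherits(profile, "individual_profile"),
            inherits(group, "group_profile"),
            inherits(meta, "recording_meta"))
  if (!inherits(script, "ethogram_script") || nrow(script) == 0)
    ethocv_stop("ethocv_validation_error", "script must be non-empty")
  bad <- setdiff(script$behaviour, names(models))
  if (length(bad))
    ethocv_stop("ethocv_class_error", "no model for behaviour(s): %s",
                paste(unique(bad), collapse = ", "))

  rate <- meta$sampling_rate
  ends <- cumsum(script$duration)
  starts <- c(0, ends[-length(ends)])
  n_total <- floor(ends[length(ends)] * rate)
  t <- (seq_len(n_total) - 1) / rate
  X <- matrix(0, n_total, 9, dimnames = list(NULL, CHANNELS9))
  Roff <- euler_rotation(profile$orientation_offset)

  with_seed(seed, {
    for (k in seq_len(nrow(script))) {
      b <- script$behaviour[k]
      mod <- models[[b]]
      # half-open interval [start, end): sample times in it
      sel <- which(t >= starts[k] - 1e-12 & t < ends[k] - 1e-12)
      if (!length(sel)) next
      tk <- t[sel]
      n <- length(sel)

      f_group <- mod$osc_frequency / group$size_scale
      f <- f_group * profile$freq_multiplier
      if (b == "run") f <- max(f + group$run_frequency_shift, 0)
      # acceleration amplitude carries the physical f^2 consequence of any
      # frequency deviation from the group baseline (a_peak ~ (2*pi*f)^2 *
      # displacement): a slower run is also a gentler run
      ratio <- if (f_group > 0) f / f_group else 1
      amp <- mod$osc_amplitude * profile$amplitude_multiplier *
        group$size_scale * ratio^2
      grav <- as.vector(Roff %*% mod$gravity_orientation)
      base_ang <- c(atan2(grav[2], grav[3]),
                    -asin(max(-1, min(1, grav[1]))),
                    profile$orientation_offset[3])

      phase <- runif(1, 0, 2 * pi)
      axis_phase <- c(0, pi / 2, pi)
      osc <- vapply(1:3, function(a)
        sin(2 * pi * f * tk + phase + axis_phase[a]), numeric(n))

      acc <- sweep(osc, 2, amp, `*`)
      acc <- sweep(acc, 2, grav, `+`) +
        matrix(rnorm(3 * n, 0, mod$noise_sd), n, 3)

      # bursts: short decaying transients on the acceleration channels
      if (mod$burstiness > 0) {
        events <- which(runif(n) < mod$burstiness / rate)
        pulse <- 0.5 * profile$amplitude_multiplier *
          exp(-(0:round(0.15 * rate)) / (0.05 * rate))
        for (e in events) {
          idx <- e:min(e + length(pulse) - 1, n)
          sgn <- sign(runif(1) - 0.5)
          acc[idx, 1:3] <- acc[idx, 1:3] + sgn * pulse[seq_along(idx)]
        }
      }

      gyr_amp <- 2 * mod$osc_amplitude * profile$amplitude_multiplier *
        group$size_scale * ratio  # angular rate scales with f, not f^2
      gyr <- vapply(1:3, function(a)
        gyr_amp[a] * sin(2 * pi * f * tk + phase + axis_phase[a] + pi / 2),
        numeric(n)) + matrix(rnorm(3 * n, 0, 2 * mod$noise_sd), n, 3)

      att_osc <- 0.10 * mean(amp) * sin(2 * pi * f * tk + phase)
      att <- matrix(base_ang, n, 3, byrow = TRUE) + att_osc +
        matrix(rnorm(3 * n, 0, 0.01), n, 3)

      X[sel, 1:3] <- acc
      X[sel, 4:6] <- gyr
      X[sel, 7:9] <- att
    }
  })

  recording <- data.frame(t = t, X, check.names = FALSE)
  class(recording) <- c("inertial_recording", "data.frame")
  attr(recording, "meta") <- meta
  labels <- data.frame(start_s = starts, end_s = ends,
                       behaviour = script$behaviour, stringsAsFactors = FALSE)
  class(labels) <- c("label_track", "data.frame")
  list(recording = recording, labels = labels)
}

#' Generate a cohort of individuals from one group
#'
#' Draws `n_individuals` signal signatures at the given individual effect
#' and synthesizes one recording per individual from the same script
#' template. Per-individual seeds are derived deterministically from the
#' master seed, so the cohort is reproducible and grows stably.
#'
#' @param n_individuals >= 2 (per-individual cross-validation needs at
#'   least two animals).
#' @param group a [group_profile()].
#' @param script an [ethogram_script()] used for every individual.
#' @param individual_effect lambda >= 0, see
#'   [sample_individual_profile()].
#' @param seed master seed.
#' @param sampling_rate Hz, default 50.
#' @param models behaviour models.
#' @return List of per-individual lists with elements `profile`,
#'   `recording`, `labels`; class `cohort`.
#' @export
generate_cohort <- function(n_individuals, group, script, individual_effect,
                            seed, sampling_rate = 50,
                            models = default_behaviour_models()) {
  if (!is_scalar_num(n_individuals) || n_individuals < 2)
    ethocv_stop("ethocv_validation_error",
                "n_individuals must be >= 2 (got %s)", n_individuals)
  out <- lapply(seq_len(n_individuals), function(i) {
    id <- sprintf("%s_%02d", group$group_id, i)
    profile <- sample_individual_profile(group, individual_effect,
                                         seed = derive_seed(seed, 1, i),
                                         individual_id = id)
    meta <- recording_meta(id, group$group_id, sampling_rate)
    rec <- generate_recording(profile, group, script, meta,
                              seed = derive_seed(seed, 2, i), models = models)
    c(list(profile = profile), rec)
  })
  structure(out, class = "cohort", group = group,
            individual_effect = individual_effect, seed = seed)
}
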