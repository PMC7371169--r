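# The eight-class canine ethogram and the per-behaviour signal models the
# simulator draws from.

#' The eight behaviour classes
#'
#' Returns the ethogram in its natural order: three passive postures, three
#' locomotion gaits ordered by speed, and two feeding behaviours. Models sort
#' classes lexicographically; this order is for presentation (confusion
#' matrices, plots).
#'
#' @return Character vector of length 8.
#' @export
ethogram_classes <- function() {
  c("lay", "sit", "stand", "walk", "trot", "run", "eat", "drink")
}

PASSIVE_CLASSES <- c("lay", "sit", "stand")
GAIT_CLASSES <- c("walk", "trot", "run")
FEEDING_CLASSES <- c("eat", "drink")
CHANNELS9 <- c("ax", "ay", "az", "gx", "gy", "gz", "roll", "pitch", "yaw")

#' Behaviour signal model
#'
#' Parametrizes the synthetic collar signal of one behaviour: a baseline
#' gravity direction in the device frame (the posture), a sinusoidal
#' oscillation (the movement), additive Gaussian noise, and - for feeding
#' behaviours - randomly timed transient bursts.
#'
#' @param behaviour_name one of [ethogram_classes()].
#' @param gravity_orientation unit 3-vector: gravity direction in the device
#'   frame (dimensionless, g-units).
#' @param osc_frequency fundamental oscillation frequency in Hz (>= 0).
#' @param osc_amplitude per-axis oscillation amplitudes in g (3-vector, >= 0).
#' @param noise_sd additive noise standard deviation in g (>= 0).
#' @param burstiness expected transient bursts per second (eat/drink chewing
#'   and lapping); in `[0, 1]`.
#' @return An object of class `behaviour_model`.
#' @export
behaviour_model <- function(behaviour_name, gravity_orientation, osc_frequency,
                            osc_amplitude, noise_sd, burstiness = 0) {
  if (!behaviour_name %in% ethogram_classes())
    ethocv_stop("ethocv_class_error", "unknown behaviour '%s'", behaviour_name)
  stopifnot(length(gravity_orientation) == 3,
            is_scalar_num(osc_frequency), osc_frequency >= 0,
            length(osc_amplitude) == 3, all(osc_amplitude >= 0),
            is_scalar_num(noise_sd), noise_sd >= 0,
            is_scalar_num(burstiness), burstiness >= 0, burstiness <= 1)
  nrm <- sqrt(sum(gravity_orientation^2))
  if (abs(nrm - 1) > 1e-9)
    ethocv_stop("ethocv_validation_error",
                "gravity_orientation must have unit norm (got %.12f)", nrm)
  structure(list(behaviour_name = behaviour_name,
                 gravity_orientation = as.double(gravity_orientation),
                 osc_frequency = osc_frequency,
                 osc_amplitude = as.double(osc_amplitude),
                 noise_sd = noise_sd, burstiness = burstiness),
            class = "behaviour_model")
}

unitv <- function(v) v / sqrt(sum(v^2))

#' Default behaviour models
#'
#' The stated world of the simulator: passive postures differ mainly in
#' collar attitude and are nearly quiescent; gaits share an upright posture
#' and differ in fundamental frequency (walk 1.5 Hz < trot 2.5 Hz < run
#' 3.5 Hz) and amplitude; feeding behaviours are head-down postures with
#' moderate oscillation plus transient bursts.
#'
#' @param quiescence_bound maximum oscillation amplitude (g) allowed for the
#'   passive postures; validated, default 0.05.
#' @return Named list of [behaviour_model()] objects, one per class.
#' @export
default_behaviour_models <- function(quiescence_bound = 0.05) {
  m <- list(
    lay   = behaviour_model("lay",   unitv(c(0, 0.70, 0.70)), 0.25,
                            c(0.010, 0.010, 0.012), 0.020),
    sit   = behaviour_model("sit",   unitv(c(0.50, 0, 0.87)), 0.35,
                            c(0.018, 0.014, 0.020), 0.020),
    stand = behaviour_model("stand", c(0, 0, 1), 0.50,
                            c(0.030, 0.020, 0.030), 0.025),
    walk  = behaviour_model("walk",  c(0, 0, 1), 1.50,
                            c(0.15, 0.10, 0.20), 0.050),
    trot  = behaviour_model("trot",  c(0, 0, 1), 2.50,
                            c(0.30, 0.20, 0.45), 0.050),
    run   = behaviour_model("run",   c(0, 0, 1), 3.50,
                            c(0.50, 0.35, 0.80), 0.050),
    eat   = behaviour_model("eat",   unitv(c(0.87, 0, 0.50)), 1.20,
                            c(0.12, 0.08, 0.15), 0.040, burstiness = 0.6),
    drink = behaviour_model("drink", unitv(c(0.94, 0, 0.34)), 4.00,
                            c(0.06, 0.05, 0.10), 0.040, burstiness = 0.3)
  )
  validate_behaviour_models(m, quiescence_bound)
  m
}

#' Validate a full set of behaviour models
#'
#' Checks the three structural constraints the downstream analysis relies
#' on: one model per ethogram class, gait frequencies ordered
#' walk < trot < run, and passive-posture amplitudes below the quiescence
#' bound.
#'
#' @param models named list of [behaviour_model()].
#' @param quiescence_bound amplitude bound (g) for lay/sit/stand.
#' @return `models`, invisibly.
#' @export
validate_behaviour_models <- function(models, quiescence_bound = 0.05) {
  missing <- setdiff(ethogram_classes(), names(models))
  if (length(missing))
    ethocv_stop("ethocv_validation_error", "missing behaviour models: %s",
                paste(missing, collapse = ", "))
  f <- vapply(models[GAIT_CLASSES], `[[`, 0, "osc_frequency")
  if (!(f["walk"] < f["trot"] && f["trot"] < f["run"]))
    ethocv_stop("ethocv_validation_error",
                "gait frequencies must be ordered walk < trot < run")
  for (b in PASSIVE_CLASSES)
    if (max(models[[b]]$osc_amplitude) > quiescence_bound)
      ethocv_stop("ethocv_validation_error",
                  "passive behaviour '%s' exceeds quiescence bound %.3f g",
                  b, quiescence_bound)
  invisible(models)
}
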