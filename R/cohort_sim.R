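# Strategy presets and cohort simulation. The preset numeric ranges are
# design constants chosen for plausible magnitude (no subject-level raw
# kinematics exist to calibrate against); only the DIRECTION of the
# healthy-vs-stroke differences is anchored to the published group pattern:
# stroke reaches substitute trunk flexion for shoulder/elbow excursion in
# forward reach, and shoulder abduction + girdle elevation for shoulder/
# elbow flexion in hand-to-mouth reach.

# One truncated-normal end-value spec per DOF per task.
#' @noRd
tn <- function(mean, sd, lower, upper) {
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

#' Strategy preset for cohort simulation
#'
#' Bundles, for each task, a truncated-normal distribution over each
#' degree-of-freedom end value (degrees; `girdle_elevation` mm), plus the
#' marker-noise level. The built-in `healthy` preset is arm-dominant (large
#' shoulder/elbow excursion, trunk DOFs near zero); the `stroke` preset has
#' reduced shoulder/elbow excursion with elevated trunk flexion (forward
#' reach) and elevated abduction and girdle elevation (hand-to-mouth).
#' Default marker noise is the capture device's typical per-axis error
#' (2.0, 1.1, 1.65 mm on X, Y, Z).
#'
#' @param name `"healthy"` or `"stroke"`.
#' @param noise_sd Marker noise SD per axis, mm.
#' @param uel_mean,uel_sd Upper-extremity length distribution, mm (defaults
#'   match the reference cohorts: healthy 717 (39), stroke 694 (51)).
#' @return An object of class `strategy_preset`.
#' @export
strategy_preset <- function(name = c("healthy", "stroke"),
                            noise_sd = c(2.0, 1.1, 1.65),
                            uel_mean = NULL, uel_sd = NULL) {
  name <- match.arg(name)
  if (any(noise_sd < 0)) {
    stop_reachcomp("noise_sd must be non-negative", "reachcomp_parameter_error")
  }
  if (name == "healthy") {
    fw <- list(shoulder_flexion = tn(65, 7, 45, 80),
               elbow_flexion = tn(15, 7, 0, 35),       # 90 deg start -> extension
               trunk_flexion = tn(2, 1.5, 0, 6),
               trunk_rotation = tn(8, 3, 2, 15))
    hm <- list(shoulder_flexion = tn(15, 5, 5, 30),
               elbow_flexion = tn(150, 8, 120, 170),   # 90 deg start -> flexion
               shoulder_abduction = tn(2, 2, 0, 8),
               girdle_elevation = tn(8, 4, 0, 18),
               neck_flexion = tn(0, 0.5, -2, 2))
    uel <- c(if (is.null(uel_mean)) 717 else uel_mean,
             if (is.null(uel_sd)) 39 else uel_sd)
  } else {
    fw <- list(shoulder_flexion = tn(30, 10, 10, 55),
               elbow_flexion = tn(50, 12, 25, 80),     # reduced extension
               trunk_flexion = tn(18, 10, 0, 45),      # compensatory lean
               trunk_rotation = tn(10, 4, 2, 20))
    hm <- list(shoulder_flexion = tn(10, 5, 0, 25),
               elbow_flexion = tn(125, 10, 100, 150),  # reduced flexion
               shoulder_abduction = tn(28, 10, 8, 55), # compensatory abduction
               girdle_elevation = tn(32, 10, 8, 60),   # compensatory shrug
               neck_flexion = tn(3, 3, -2, 12))
    uel <- c(if (is.null(uel_mean)) 694 else uel_mean,
             if (is.null(uel_sd)) 51 else uel_sd)
  }
  structure(list(name = name, noise_sd = rep(noise_sd, length.out = 3),
                 forward_reach = fw, hand_to_mouth = hm,
                 uel_mean = uel[[1]], uel_sd = uel[[2]]),
            class = "strategy_preset")
}

# Truncated-normal draw by rejection (bounds are anatomical, never extreme,
# so acceptance is high).
#' @noRd
rtruncnorm1 <- function(spec) {
  if (spec$sd == 0) return(min(max(spec$mean, spec$lower), spec$upper))
  repeat {
    x <- stats::rnorm(1, spec$mean, spec$sd)
    if (x >= spec$lower && x <= spec$upper) return(x)
  }
}

# Joint program for one subject draw of a preset/task.
#' @noRd
preset_program <- function(preset, task, duration = 1.2) {
  specs <- preset[[task]]
  args <- lapply(names(specs), function(d) {
    end <- rtruncnorm1(specs[[d]])
    c(rest_pose()[[d]], end)
  })
  names(args) <- names(specs)
  do.call(joint_program, c(args, list(duration = duration)))
}

#' Simulate a cohort of subjects
#'
#' Draws `n` subjects from a strategy preset (seeded), each with its own
#' upper-extremity length (the chain is scaled accordingly) and per-DOF end
#' values, and simulates one trial per subject per task. Stroke subjects
#' reach with the left side (as in the reference cohort, where every stroke
#' participant used the left hand); healthy subjects with the right.
#'
#' @param preset A [strategy_preset()].
#' @param n Number of subjects (reference cohort sizes: 20 healthy,
#'   10 stroke).
#' @param config Base [chain_config()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param tasks Tasks to simulate per subject.
#' @return List with `trials` (list of [trial_recording()], one per subject
#'   per task) and `subjects` (a `data.frame` of [subject_record()] rows).
#' @export
simulate_cohort <- function(preset, n, config = chain_config(), seed = NULL,
                            tasks = c("forward_reach", "hand_to_mouth")) {
  stopifnot(inherits(preset, "strategy_preset"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  side <- if (preset$name == "stroke") "left" else "right"
  prefix <- if (preset$name == "stroke") "S" else "H"
  trials <- list()
  subjects <- NULL
  for (i in seq_len(n)) {
    sid <- sprintf("%s%02d", prefix, i)
    uel <- max(500, stats::rnorm(1, preset$uel_mean, preset$uel_sd))
    cfg_i <- scale_chain(config, uel)
    age <- if (preset$name == "stroke") stats::rnorm(1, 70.7, 13.8) else stats::rnorm(1, 26.5, 4.9)
    subjects <- rbind(subjects, subject_record(
      subject_id = sid, group = preset$name, age = round(age, 1),
      sex = sample(c("F", "M"), 1),
      affected_side = if (preset$name == "stroke") side else NA_character_,
      fma_total = if (preset$name == "stroke")
        min(66, max(0, round(stats::rnorm(1, 52.1, 10.7)))) else NA_real_,
      upper_extremity_length = uel))
    for (task in tasks) {
      prog <- preset_program(preset, task)
      noise_seed <- sample.int(.Machine$integer.max, 1)
      trials[[paste(sid, task, sep = ".")]] <- simulate_trial(
        cfg_i, prog, task = task, noise_sd = preset$noise_sd,
        seed = noise_seed, subject_id = sid, reaching_side = side)
    }
  }
  list(trials = trials, subjects = subjects)
}
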