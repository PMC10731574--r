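# Seated trunk-girdle-arm-head kinematic chain: joint-angle programs ->
# marker trajectories. Serves both as the synthetic-data generator and as
# the analytic ground truth for the decomposition.

CHAIN_DOFS <- c("trunk_flexion", "trunk_rotation", "girdle_elevation",
                "shoulder_flexion", "shoulder_abduction", "elbow_flexion",
                "neck_flexion")

# Rest posture of the protocol: hand on the start table, shoulder flexion 0,
# elbow flexion 90 degrees. Angles in degrees, girdle_elevation in mm.
#' @noRd
rest_pose <- function() {
  c(trunk_flexion = 0, trunk_rotation = 0, girdle_elevation = 0,
    shoulder_flexion = 0, shoulder_abduction = 0, elbow_flexion = 90,
    neck_flexion = 0)
}

#' Configure the kinematic chain
#'
#' Segment lengths of the seated chain, in mm. Defaults are sized so that
#' the acromion-to-MP distance with the elbow extended (upper arm + forearm
#' = 630 mm) sits at about 88% of a 717 mm upper-extremity length — the MP
#' joint lies roughly 88% of the way from acromion to fingertip — matching
#' adult anthropometry.
#'
#' @param trunk_length Trochanter to C7, mm.
#' @param shoulder_offset C7 to acromion, lateral, mm.
#' @param upper_arm_length Acromion to humeral epicondyle, mm.
#' @param forearm_length Epicondyle to index MP joint, mm.
#' @param chin_offset Length-2 vector: C7 to chin, (forward, up) mm.
#' @param upper_extremity_length Declared acromion-to-fingertip length, mm;
#'   the arm segments must be consistent with it (within 5% of 88% of it).
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(trunk_length = 450, shoulder_offset = 180,
                         upper_arm_length = 300, forearm_length = 330,
                         chin_offset = c(60, 120),
                         upper_extremity_length = 717) {
  lens <- c(trunk_length, shoulder_offset, upper_arm_length, forearm_length,
            upper_extremity_length)
  if (any(lens <= 0)) {
    stop_reachcomp("all segment lengths must be positive", "reachcomp_parameter_error")
  }
  arm <- upper_arm_length + forearm_length
  if (abs(arm - 0.88 * upper_extremity_length) > 0.05 * upper_extremity_length) {
    stop_reachcomp(sprintf(
      "upper_arm + forearm = %.0f mm inconsistent with upper_extremity_length %.0f mm (expect ~88%% of it within 5%%)",
      arm, upper_extremity_length), "reachcomp_parameter_error")
  }
  structure(list(trunk_length = trunk_length, shoulder_offset = shoulder_offset,
                 upper_arm_length = upper_arm_length,
                 forearm_length = forearm_length,
                 chin_offset = chin_offset,
                 upper_extremity_length = upper_extremity_length),
            class = "chain_config")
}

#' Scale a chain to a subject's upper-extremity length
#' @param config A [chain_config()].
#' @param upper_extremity_length Target length, mm.
#' @return Scaled [chain_config()].
#' @export
scale_chain <- function(config, upper_extremity_length) {
  s <- upper_extremity_length / config$upper_extremity_length
  chain_config(config$trunk_length * s, config$shoulder_offset * s,
               config$upper_arm_length * s, config$forearm_length * s,
               config$chin_offset * s, upper_extremity_length)
}

#' Minimum-jerk profile
#'
#' Quintic rest-to-rest time course, the standard model for smooth
#' point-to-point human movement: fraction of travel completed at time `t`
#' for a movement starting at `onset` and lasting `duration`.
#'
#' @param t Time(s), seconds (vectorized).
#' @param onset Movement onset, seconds.
#' @param duration Movement duration, seconds (> 0).
#' @return Fractions in `[0, 1]`; 0 before onset, 1 after the movement,
#'   `10*tau^3 - 15*tau^4 + 6*tau^5` in between. Monotone non-decreasing with
#'   zero velocity at both ends.
#' @export
minimum_jerk_profile <- function(t, onset = 0, duration = 1) {
  if (duration <= 0) {
    stop_reachcomp("duration must be positive", "reachcomp_parameter_error")
  }
  tau <- pmin(pmax((t - onset) / duration, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Define a joint-angle program
#'
#' A program gives each degree of freedom a start value, end value, onset
#' and duration; between onset and onset+duration the value follows a
#' minimum-jerk profile. Unspecified DOFs stay at the rest posture
#' (shoulder flexion 0, elbow flexion 90 degrees, everything else 0).
#' Angles in degrees; `girdle_elevation` in mm.
#'
#' @param ... Named DOF specs: either a single end value, a length-2 vector
#'   `c(start, end)`, or a list with elements `start`, `end`, `onset`,
#'   `duration`.
#' @param onset,duration Defaults applied to DOFs that do not set their own
#'   (seconds).
#' @return An object of class `joint_program`.
#' @examples
#' joint_program(shoulder_flexion = 60, elbow_flexion = c(90, 15))
#' @export
joint_program <- function(..., onset = 0, duration = 1) {
  specs <- list(...)
  bad <- setdiff(names(specs), CHAIN_DOFS)
  if (length(bad)) {
    stop_reachcomp(sprintf("unknown degree(s) of freedom: %s",
                           paste(bad, collapse = ", ")),
                   "reachcomp_parameter_error")
  }
  rest <- rest_pose()
  dofs <- lapply(CHAIN_DOFS, function(d) {
    s <- specs[[d]]
    base <- list(start = rest[[d]], end = rest[[d]], onset = onset,
                 duration = duration)
    if (is.null(s)) return(base)
    if (is.list(s)) {
      base[names(s)] <- s
    } else if (length(s) == 1L) {
      base$end <- s
    } else if (length(s) == 2L) {
      base$start <- s[[1]]; base$end <- s[[2]]
    } else {
      stop_reachcomp(sprintf("bad spec for %s", d), "reachcomp_parameter_error")
    }
    if (base$duration <= 0) {
      stop_reachcomp("durations must be positive", "reachcomp_parameter_error")
    }
    base
  })
  names(dofs) <- CHAIN_DOFS
  structure(list(dofs = dofs), class = "joint_program")
}

#' @noRd
program_span <- function(program) {
  max(vapply(program$dofs, function(d) d$onset + d$duration, numeric(1)))
}

# Pose (named DOF vector) at time t.
#' @noRd
program_pose <- function(program, t) {
  vapply(program$dofs, function(d) {
    d$start + (d$end - d$start) * minimum_jerk_profile(t, d$onset, d$duration)
  }, numeric(length(t)))
}

#' Forward kinematics: marker positions from a pose
#'
#' Places the 10-marker set for a seated subject reaching with the right
#' (canonical) side. The reaching-side trochanter sits at the origin; the
#' trunk pitches forward by `trunk_flexion` and yaws by `trunk_rotation`;
#' the acromion adds a lateral shoulder offset in the trunk frame plus
#' `girdle_elevation` along trunk-vertical; the upper arm rotates by
#' shoulder flexion (about the lateral axis) then abduction (about the
#' forward axis); the forearm adds elbow flexion; the chin hangs off C7,
#' rotated forward/down by neck flexion. The non-reaching (left) side is
#' placed at rest riding on the trunk frame.
#'
#' @param config A [chain_config()].
#' @param pose Named numeric vector over [the DOFs][joint_program()]
#'   (degrees; `girdle_elevation` mm). Missing entries default to rest.
#' @return Named list of length-3 position vectors (mm), one per marker.
#' @export
marker_positions_from_pose <- function(config, pose = rest_pose()) {
  stopifnot(inherits(config, "chain_config"))
  p <- rest_pose()
  p[names(pose)] <- pose
  pos <- chain_positions(config,
                         matrix(p, 1, length(p), dimnames = list(NULL, names(p))))
  lapply(pos, function(m) { v <- m[1, ]; names(v) <- c("X", "Y", "Z"); v })
}

# Vectorized forward kinematics: poses is n x 7 (columns CHAIN_DOFS).
# Returns named list of n x 3 matrices. Right = reaching side.
#' @noRd
chain_positions <- function(config, poses) {
  deg <- pi / 180
  tf <- poses[, "trunk_flexion"] * deg
  tr <- poses[, "trunk_rotation"] * deg
  ge <- poses[, "girdle_elevation"]
  sf <- poses[, "shoulder_flexion"] * deg
  ab <- poses[, "shoulder_abduction"] * deg
  ef <- poses[, "elbow_flexion"] * deg
  nf <- poses[, "neck_flexion"] * deg

  cf <- cos(tf); sfl <- sin(tf)
  cy <- cos(tr); sy <- sin(tr)
  n <- nrow(poses)
  troch <- matrix(0, n, 3)

  # trunk frame basis (world coordinates); e_z = trunk-vertical
  ex <- cbind(cy, sy, 0)
  ey <- cbind(-sy * cf, cy * cf, -sfl)
  ez <- cbind(-sy * sfl, cy * sfl, cf)

  c7 <- config$trunk_length * ez
  acr <- c7 + config$shoulder_offset * ex + ge * ez
  acr_l <- c7 - config$shoulder_offset * ex

  # arm vectors in the trunk frame, then mapped through the basis
  to_world <- function(local) {
    # local: n x 3 in trunk frame
    local[, 1] * ex + local[, 2] * ey + local[, 3] * ez
  }
  L_ua <- config$upper_arm_length
  L_fa <- config$forearm_length
  arm_local <- L_ua * cbind(cos(sf) * sin(ab), sin(sf), -cos(sf) * cos(ab))
  epi <- acr + to_world(arm_local)
  th <- sf + ef
  fore_local <- L_fa * cbind(cos(th) * sin(ab), sin(th), -cos(th) * cos(ab))
  mp <- epi + to_world(fore_local)

  # left arm at rest (hanging, elbow 90), riding on the trunk frame
  epi_l <- acr_l + to_world(matrix(rep(c(0, 0, -L_ua), each = n), n))
  mp_l <- epi_l + to_world(matrix(rep(c(0, L_fa, 0), each = n), n))

  f_off <- config$chin_offset[[1]]; u_off <- config$chin_offset[[2]]
  chin_local <- cbind(0, f_off * cos(nf) + u_off * sin(nf),
                      -f_off * sin(nf) + u_off * cos(nf))
  chin <- c7 + to_world(chin_local)

  pelvis_halfwidth <- 170  # seated pelvis width; static, analysis never uses it
  troch_l <- cbind(-2 * pelvis_halfwidth + troch[, 1], troch[, 2], troch[, 3])

  out <- list(CHIN = chin, C7 = c7,
              ACROMION_L = acr_l, ACROMION_R = acr,
              EPICONDYLE_L = epi_l, EPICONDYLE_R = epi,
              MP_L = mp_l, MP_R = mp,
              TROCHANTER_L = troch_l, TROCHANTER_R = troch)
  lapply(out, function(m) { colnames(m) <- c("X", "Y", "Z"); m })
}

#' Simulate a reaching trial
#'
#' Samples the kinematic chain along a joint program at `sampling_rate`,
#' with rest padding before and after the movement, and adds independent
#' Gaussian marker noise per marker, axis and frame (emulating optical
#' capture error).
#'
#' @param config A [chain_config()].
#' @param program A [joint_program()].
#' @param task `"forward_reach"` or `"hand_to_mouth"` (metadata for the
#'   decomposition dispatch).
#' @param sampling_rate Hz (protocol reference 60).
#' @param noise_sd Marker noise SD in mm: scalar or length-3 `(X, Y, Z)`.
#'   The capture device's stated absolute error is 1.5-2.4 mm lateral,
#'   0.5-1.7 mm anterior, 1.6-1.7 mm vertical.
#' @param seed Integer seed for the noise (omit for unseeded randomness).
#' @param rest_padding Seconds of quiet rest before and after the program.
#' @param subject_id,reaching_side Trial metadata. Left-side trials are
#'   generated by mirroring the canonical right-side chain.
#' @return A [trial_recording()] with the full 10-marker set.
#' @export
simulate_trial <- function(config, program,
                           task = c("forward_reach", "hand_to_mouth"),
                           sampling_rate = 60, noise_sd = 0, seed = NULL,
                           rest_padding = 0.5, subject_id = "sim",
                           reaching_side = "right") {
  stopifnot(inherits(config, "chain_config"), inherits(program, "joint_program"))
  task <- match.arg(task)
  if (sampling_rate <= 0) {
    stop_reachcomp("sampling_rate must be positive", "reachcomp_parameter_error")
  }
  span <- program_span(program)
  tmax <- 2 * rest_padding + span
  t <- seq(0, tmax, by = 1 / sampling_rate)
  poses <- program_pose(program, t - rest_padding)
  if (is.null(dim(poses))) poses <- matrix(poses, 1, dimnames = list(NULL, CHAIN_DOFS))
  pos <- chain_positions(config, poses)

  noise_sd <- rep(noise_sd, length.out = 3)
  if (any(noise_sd < 0)) {
    stop_reachcomp("noise_sd must be non-negative", "reachcomp_parameter_error")
  }
  if (any(noise_sd > 0)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    pos <- lapply(pos, function(m) {
      m + cbind(stats::rnorm(nrow(m), 0, noise_sd[1]),
                stats::rnorm(nrow(m), 0, noise_sd[2]),
                stats::rnorm(nrow(m), 0, noise_sd[3]))
    })
  }

  trial <- trial_recording(pos, sampling_rate, task, "right",
                           subject_id = subject_id,
                           upper_extremity_length = config$upper_extremity_length,
                           source = "simulated",
                           provenance = list(seed = seed, noise_sd = noise_sd,
                                             rest_padding = rest_padding))
  if (identical(reaching_side, "left")) {
    # mirror the canonical chain into a left-handed recording
    posL <- lapply(trial$positions, function(m) { m[, "X"] <- -m[, "X"]; m })
    names(posL) <- swap_sides(names(posL))
    trial$positions <- posL
    trial$reaching_side <- "left"
  }
  trial
}

#' Analytic decomposition oracle
#'
#' Independent ground truth for the decomposition: evaluates the chain at
#' the program's exact start and end poses only and applies the
#' (trochanter-calibrated) component formulas to those endpoint positions,
#' bypassing sampling, noise, filtering and window detection entirely.
#'
#' @param config A [chain_config()].
#' @param program A [joint_program()].
#' @param task `"forward_reach"` or `"hand_to_mouth"`.
#' @return List with `total` (mm) and named `components` (mm).
#' @export
analytic_decomposition_oracle <- function(config, program,
                                          task = c("forward_reach", "hand_to_mouth")) {
  task <- match.arg(task)
  start <- vapply(program$dofs, function(d) d$start, numeric(1))
  end <- vapply(program$dofs, function(d) d$end, numeric(1))
  p0 <- marker_positions_from_pose(config, start)
  p1 <- marker_positions_from_pose(config, end)
  D <- function(mk, ax) {
    (p1[[mk]][[ax]] - p0[[mk]][[ax]]) -
      (p1[["TROCHANTER_R"]][[ax]] - p0[["TROCHANTER_R"]][[ax]])
  }
  if (task == "forward_reach") {
    d_mp <- D("MP_R", "Y"); d_acr <- D("ACROMION_R", "Y"); d_c7 <- D("C7", "Y")
    list(total = d_mp,
         components = c(shoulder_elbow = d_mp - d_acr,
                        trunk_rotation = d_acr - d_c7,
                        trunk_flexion = d_c7))
  } else {
    d_mp <- D("MP_R", "Z"); d_epi <- D("EPICONDYLE_R", "Z")
    d_acr <- D("ACROMION_R", "Z"); d_chin <- D("CHIN", "Z")
    list(total = d_mp - d_chin,
         components = c(shoulder_elbow_flexion = d_mp - d_epi,
                        shoulder_abduction = d_epi - d_acr,
                        girdle_elevation = d_acr,
                        cervical_flexion = -d_chin))
  }
}
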