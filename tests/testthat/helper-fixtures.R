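# Fixture builders shared across the suite. All fixtures are constructed in
# code; nothing binary ships with the package.

# Trial with explicitly given per-marker tracks. Tracks may be a single
# 3-vector (static marker) or an n x 3 matrix.
make_trial <- function(..., n = 10, rate = 60, task = "forward_reach",
                       side = "right", uel = NULL) {
  specs <- list(...)
  pos <- lapply(specs, function(s) {
    if (is.matrix(s)) s else matrix(s, n, 3, byrow = TRUE)
  })
  nf <- max(vapply(pos, nrow, integer(1)))
  pos <- lapply(pos, function(m) {
    if (nrow(m) == nf) m else m[rep(seq_len(nrow(m)), length.out = nf), ]
  })
  trial_recording(pos, rate, task, side, subject_id = "fix",
                  upper_extremity_length = uel)
}

# Linear ramp from p0 to p1 over n frames (3-vectors).
ramp <- function(p0, p1, n) {
  t(vapply(seq_len(n), function(i) p0 + (p1 - p0) * (i - 1) / (n - 1),
           numeric(3)))
}

# Minimum-jerk point-to-point track with rest padding, mirroring what the
# simulator produces for a single marker.
minjerk_track <- function(p0, p1, rate = 60, duration = 1, pad = 0.5) {
  t <- seq(0, duration + 2 * pad, by = 1 / rate)
  s <- minimum_jerk_profile(t, onset = pad, duration = duration)
  outer(s, p1 - p0) + matrix(p0, length(t), 3, byrow = TRUE)
}

# Full forward-reach fixture: moving MP, static everything else required.
forward_fixture <- function(mp_delta = c(0, 300, 0), n = 90, rate = 60) {
  mp <- minjerk_track(c(100, 200, 150), c(100, 200, 150) + mp_delta,
                      rate = rate, duration = 1, pad = 0.25)
  make_trial(MP_R = mp,
             ACROMION_R = c(180, 0, 450), C7 = c(0, 0, 450),
             TROCHANTER_R = c(0, 0, 0),
             n = nrow(mp), rate = rate)
}

# A small deterministic program grid over all 7 DOFs (used by several tests).
program_grid <- function(k = 3) {
  vals <- list(
    trunk_flexion = seq(0, 30, length.out = k),
    trunk_rotation = seq(0, 20, length.out = k),
    girdle_elevation = seq(0, 40, length.out = k),
    shoulder_flexion = seq(0, 70, length.out = k),
    shoulder_abduction = seq(0, 40, length.out = k),
    elbow_flexion = seq(90, 150, length.out = k),
    neck_flexion = seq(0, 15, length.out = k)
  )
  grid <- expand.grid(vals[c("trunk_flexion", "shoulder_flexion",
                             "elbow_flexion")], KEEP.OUT.ATTRS = FALSE)
  progs <- list()
  for (i in seq_len(nrow(grid))) {
    progs[[length(progs) + 1L]] <- joint_program(
      trunk_flexion = grid$trunk_flexion[[i]],
      shoulder_flexion = grid$shoulder_flexion[[i]],
      elbow_flexion = c(90, grid$elbow_flexion[[i]]))
  }
  progs
}

# Random joint program under a fixed RNG state (caller seeds).
random_program <- function(task) {
  if (task == "forward_reach") {
    joint_program(
      shoulder_flexion = stats::runif(1, 20, 80),
      elbow_flexion = c(90, stats::runif(1, 10, 70)),
      trunk_flexion = stats::runif(1, 0, 30),
      trunk_rotation = stats::runif(1, 0, 20),
      duration = stats::runif(1, 0.8, 1.6))
  } else {
    joint_program(
      shoulder_flexion = stats::runif(1, 0, 25),
      elbow_flexion = c(90, stats::runif(1, 110, 165)),
      shoulder_abduction = stats::runif(1, 0, 40),
      girdle_elevation = stats::runif(1, 0, 50),
      neck_flexion = stats::runif(1, -3, 15),
      duration = stats::runif(1, 0.8, 1.6))
  }
}
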