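# Reach-window detection, side canonicalization, and the pelvis-calibrated
# displacement primitive shared by both task decompositions.

#' Construct a reach window
#'
#' @param start_frame,end_frame 1-based frame indices, `start_frame <
#'   end_frame <= n_frames`.
#' @param peak_speed Peak end-effector tangential speed (mm/s) found during
#'   detection, if any.
#' @param detection_rule Free-text description of how the window was found.
#' @param clamped Logical: was the window clamped to the trial bounds because
#'   the trial starts or ends mid-movement?
#' @return An object of class `reach_window`.
#' @export
reach_window <- function(start_frame, end_frame, peak_speed = NA_real_,
                         detection_rule = "manual", clamped = FALSE) {
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  if (start_frame < 1L || start_frame >= end_frame) {
    stop_reachcomp("need 1 <= start_frame < end_frame", "reachcomp_format_error")
  }
  structure(list(start_frame = start_frame, end_frame = end_frame,
                 peak_speed = peak_speed, detection_rule = detection_rule,
                 clamped = clamped),
            class = "reach_window")
}

#' @export
print.reach_window <- function(x, ...) {
  cat(sprintf("<reach_window> frames %d..%d (peak speed %.1f mm/s, %s%s)\n",
              x$start_frame, x$end_frame, x$peak_speed, x$detection_rule,
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

# Tangential speed (mm/s) of a marker via central differences.
#' @noRd
marker_speed <- function(trial, marker) {
  m <- trial$positions[[marker]]
  n <- nrow(m)
  dt <- 1 / trial$sampling_rate
  v <- matrix(NA_real_, n, 3)
  v[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * dt)
  v[1, ] <- (m[2, ] - m[1, ]) / dt
  v[n, ] <- (m[n, ] - m[n - 1, ]) / dt
  sqrt(rowSums(v^2))
}

#' Detect the reach window by end-effector speed threshold
#'
#' Movement onset/offset by the usual velocity-threshold rule, anchored at
#' the speed peak: the reach is the sustained run of frames during which the
#' end-effector (reaching-side MP marker) tangential speed exceeds
#' `threshold_fraction` of its peak and which contains that peak. The window
#' starts at the last frame before the speed crosses the threshold (staying
#' above it for at least `sustain` frames) and ends at the first frame after
#' it falls back below (staying below for `sustain` frames); shorter
#' crossings in either direction are treated as jitter, so noise blips at
#' rest cannot open or close the window. If the trial begins or ends
#' mid-movement the window is clamped to the trial bounds and flagged.
#'
#' @param trial A [trial_recording()] (filter first for noisy data).
#' @param threshold_fraction Fraction of peak speed (default 0.05). `0` gives
#'   the limiting window spanning all moving frames.
#' @param sustain Number of consecutive frames the speed must stay across
#'   the threshold (default 3; suppresses noise-induced jitter).
#' @param min_peak_speed Absolute floor (mm/s, default 20) below which the
#'   trial is declared motionless.
#' @return A [reach_window()].
#' @export
detect_reach_window <- function(trial, threshold_fraction = 0.05,
                                sustain = 3L, min_peak_speed = 20) {
  stopifnot(inherits(trial, "trial_recording"))
  mp <- sided_marker("MP", trial$reaching_side)
  if (!mp %in% names(trial$positions)) {
    stop_reachcomp(sprintf("end-effector marker %s absent", mp),
                   "reachcomp_marker_error")
  }
  sp <- marker_speed(trial, mp)
  peak <- max(sp, na.rm = TRUE)
  if (!is.finite(peak) || peak < min_peak_speed) {
    stop_reachcomp(sprintf("no movement: peak speed %.2f mm/s below floor %g mm/s",
                           peak, min_peak_speed), "reachcomp_no_movement_error")
  }
  thr <- threshold_fraction * peak
  above <- !is.na(sp) & sp > thr
  n <- length(above)
  # Suppress jitter: crossings shorter than `sustain` frames do not count,
  # in either direction (a blip above the threshold at rest is not an onset;
  # a dip below it mid-movement is not an offset).
  drop_short_runs <- function(flags, value) {
    r <- rle(flags)
    r$values[r$values == value & r$lengths < sustain] <- !value
    inverse.rle(r)
  }
  above <- drop_short_runs(above, TRUE)
  above <- drop_short_runs(above, FALSE)
  # The reach is the sustained above-threshold run containing the peak.
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peak_frame <- which.max(sp)
  k <- which(r$values & starts <= peak_frame & ends >= peak_frame)
  if (!length(k)) {
    stop_reachcomp("no sustained movement found around the speed peak",
                   "reachcomp_no_movement_error")
  }
  clamped <- FALSE
  start_frame <- starts[[k]] - 1L           # last frame before the crossing
  if (start_frame < 1L) { start_frame <- 1L; clamped <- TRUE }
  end_frame <- ends[[k]] + 1L               # first frame back below threshold
  if (end_frame > n) { end_frame <- n; clamped <- TRUE }
  reach_window(start_frame, end_frame, peak_speed = peak,
               detection_rule = sprintf(
                 "speed > %.3g x peak sustained %d frames", threshold_fraction, sustain),
               clamped = clamped)
}

#' Canonicalize the reaching side to the right
#'
#' Left-side trials are mirrored so that cohorts mixing left- and right-hand
#' reaches are comparable: X coordinates are negated and `_L`/`_R` marker
#' names swapped. The decompositions use only Y and Z, so mirroring never
#' changes a component. Idempotent on right-side trials.
#'
#' @param trial A [trial_recording()].
#' @return Canonical (right-side) trial.
#' @export
mirror_to_canonical_side <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  if (trial$reaching_side == "right") return(trial)
  pos <- lapply(trial$positions, function(m) { m[, "X"] <- -m[, "X"]; m })
  names(pos) <- swap_sides(names(pos))
  trial$positions <- pos
  trial$reaching_side <- "right"
  trial$provenance$mirrored <- TRUE
  trial
}

#' Pelvis-calibrated marker displacement
#'
#' The primitive of both decompositions: the start-to-end displacement of a
#' marker on one axis, minus the displacement of the reaching-side greater
#' trochanter over the same window. Subtracting the pelvis reference cancels
#' any whole-body translation (e.g. the seat or pelvis shifting), leaving
#' only motion of the body chain above the pelvis.
#'
#' @param trial A [trial_recording()] (positions as given, i.e. filtered if
#'   the pipeline filtered them).
#' @param marker Marker name.
#' @param axis `"X"`, `"Y"` or `"Z"`.
#' @param window A [reach_window()].
#' @return Signed displacement in mm.
#' @export
pelvis_calibrated_displacement <- function(trial, marker, axis, window) {
  stopifnot(inherits(trial, "trial_recording"), inherits(window, "reach_window"))
  assert_marker_name(marker)
  axis <- match.arg(axis, c("X", "Y", "Z"))
  troch <- sided_marker("TROCHANTER", trial$reaching_side)
  for (mk in c(marker, troch)) {
    if (!mk %in% names(trial$positions)) {
      stop_reachcomp(sprintf("marker %s absent from trial", mk),
                     "reachcomp_marker_error")
    }
    for (f in c(window$start_frame, window$end_frame)) {
      if (is.na(trial$positions[[mk]][f, axis])) {
        stop_reachcomp(sprintf("missing sample: marker %s axis %s at frame %d",
                               mk, axis, f), "reachcomp_missing_data_error")
      }
    }
  }
  d <- function(mk) {
    trial$positions[[mk]][window$end_frame, axis] -
      trial$positions[[mk]][window$start_frame, axis]
  }
  unname(d(marker) - d(troch))
}
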