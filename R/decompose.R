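# Component decomposition of reaching. Both tasks decompose the end-effector
# displacement telescopically along the marker chain, so components sum to
# the total by construction and may individually be negative.

FORWARD_COMPONENTS <- c("shoulder_elbow", "trunk_rotation", "trunk_flexion")
HTM_COMPONENTS <- c("shoulder_elbow_flexion", "shoulder_abduction",
                    "girdle_elevation", "cervical_flexion")

#' @noRd
check_denominator <- function(total, trial, denominator_mode, min_total) {
  if (denominator_mode == "measured_total") {
    if (abs(total) < min_total) {
      stop_reachcomp(sprintf(
        "degenerate trial: |total displacement| %.2f mm below floor %g mm; percent contributions undefined",
        total, min_total), "reachcomp_degenerate_error")
    }
    total
  } else {
    if (is.null(trial$upper_extremity_length)) {
      stop_reachcomp("arm_length denominator mode requires upper_extremity_length metadata",
                     "reachcomp_metadata_error")
    }
    trial$upper_extremity_length
  }
}

#' Percent contributions
#'
#' Expresses signed component displacements as percentages of a denominator.
#' With the measured total as denominator the percentages sum to 100 exactly
#' (up to rounding); individual values may be negative or exceed 100.
#'
#' @param components Numeric vector of signed displacements (mm).
#' @param denominator Total distance (mm), non-zero.
#' @return Numeric vector of signed percentages.
#' @examples
#' percent_contributions(c(250, 10, 40), 300)
#' @export
percent_contributions <- function(components, denominator) {
  if (!is.numeric(denominator) || length(denominator) != 1L || denominator == 0) {
    stop_reachcomp("denominator must be a single non-zero number",
                   "reachcomp_degenerate_error")
  }
  100 * components / denominator
}

#' Decompose a forward reach
#'
#' Splits the forward (Y-axis) displacement of the index-finger MP joint into
#' three telescoping components, each a pelvis-calibrated displacement
#' difference along the marker chain:
#' \describe{
#'   \item{shoulder_elbow}{MP relative to the acromion — shoulder flexion
#'     plus elbow extension.}
#'   \item{trunk_rotation}{acromion relative to C7 — the shoulder swinging
#'     forward as the trunk yaws.}
#'   \item{trunk_flexion}{C7 itself — the upper trunk pitching forward.}
#' }
#' The three components sum to the total exactly, by construction.
#'
#' @param trial A forward-reach [trial_recording()] (filtered, canonical side).
#' @param window A [reach_window()]; detected with [detect_reach_window()]
#'   if omitted.
#' @param denominator_mode `"measured_total"` (default; percentages sum to
#'   100) or `"arm_length"` (protocol-fidelity option using the subject's
#'   upper-extremity length as denominator).
#' @param min_total Degeneracy floor for the measured total (mm, default 20).
#' @return A `reach_decomposition` object with fields `total` (mm), per
#'   component `displacement_mm` and `percent`, and bookkeeping metadata.
#' @export
decompose_forward_reach <- function(trial, window = NULL,
                                    denominator_mode = c("measured_total", "arm_length"),
                                    min_total = 20) {
  stopifnot(inherits(trial, "trial_recording"))
  denominator_mode <- match.arg(denominator_mode)
  if (trial$task != "forward_reach") {
    stop_reachcomp("trial task is not forward_reach", "reachcomp_format_error")
  }
  if (is.null(window)) window <- detect_reach_window(trial)
  side <- trial$reaching_side
  D <- function(mk) pelvis_calibrated_displacement(trial, mk, "Y", window)
  d_mp <- D(sided_marker("MP", side))
  d_acr <- D(sided_marker("ACROMION", side))
  d_c7 <- D("C7")
  comp <- c(shoulder_elbow = d_mp - d_acr,
            trunk_rotation = d_acr - d_c7,
            trunk_flexion = d_c7)
  total <- d_mp
  denom <- check_denominator(total, trial, denominator_mode, min_total)
  new_decomposition("forward_reach", total, comp, denom, denominator_mode, trial, window)
}

#' Decompose a hand-to-mouth reach
#'
#' Splits the closure of the vertical (Z-axis) gap between the index-finger
#' MP joint and the chin into four telescoping components:
#' \describe{
#'   \item{shoulder_elbow_flexion}{MP relative to the humeral epicondyle —
#'     hand elevation through shoulder and elbow flexion.}
#'   \item{shoulder_abduction}{epicondyle relative to the acromion — elbow
#'     elevation through abduction, assuming constant acromion–epicondyle
#'     length.}
#'   \item{girdle_elevation}{the acromion itself — shoulder-girdle shrug.}
#'   \item{cervical_flexion}{the chin's drop (sign-flipped, so lowering the
#'     mouth toward the hand counts positive).}
#' }
#' The total is the vertical hand-mouth gap closed, `D(MP) + chin drop`, and
#' the four components sum to it exactly.
#'
#' @inheritParams decompose_forward_reach
#' @return A `reach_decomposition` object (see [decompose_forward_reach()]).
#' @export
decompose_hand_to_mouth <- function(trial, window = NULL,
                                    denominator_mode = c("measured_total", "arm_length"),
                                    min_total = 20) {
  stopifnot(inherits(trial, "trial_recording"))
  denominator_mode <- match.arg(denominator_mode)
  if (trial$task != "hand_to_mouth") {
    stop_reachcomp("trial task is not hand_to_mouth", "reachcomp_format_error")
  }
  if (is.null(window)) window <- detect_reach_window(trial)
  side <- trial$reaching_side
  D <- function(mk) pelvis_calibrated_displacement(trial, mk, "Z", window)
  d_mp <- D(sided_marker("MP", side))
  d_epi <- D(sided_marker("EPICONDYLE", side))
  d_acr <- D(sided_marker("ACROMION", side))
  d_chin <- D("CHIN")
  sum45 <- d_mp - d_acr
  comp5 <- d_epi - d_acr
  comp <- c(shoulder_elbow_flexion = sum45 - comp5,
            shoulder_abduction = comp5,
            girdle_elevation = d_acr,
            cervical_flexion = -d_chin)
  total <- d_mp - d_chin
  denom <- check_denominator(total, trial, denominator_mode, min_total)
  new_decomposition("hand_to_mouth", total, comp, denom, denominator_mode, trial, window)
}

#' @noRd
new_decomposition <- function(task, total, components, denominator,
                              denominator_mode, trial, window) {
  structure(list(
    task = task,
    total = unname(total),
    components = components,
    percent = percent_contributions(components, denominator),
    denominator = denominator,
    denominator_mode = denominator_mode,
    subject_id = trial$subject_id,
    window = c(start = window$start_frame, end = window$end_frame)
  ), class = "reach_decomposition")
}

#' @export
print.reach_decomposition <- function(x, ...) {
  cat(sprintf("<reach_decomposition> %s, subject %s\n", x$task, x$subject_id))
  cat(sprintf("  total: %.1f mm (denominator: %s)\n", x$total, x$denominator_mode))
  for (nm in names(x$components)) {
    cat(sprintf("  %-24s %8.1f mm  %7.2f %%\n", nm, x$components[[nm]], x$percent[[nm]]))
  }
  invisible(x)
}

#' @export
as.data.frame.reach_decomposition <- function(x, ...) {
  row <- data.frame(subject_id = x$subject_id, task = x$task,
                    total_mm = x$total, denominator_mode = x$denominator_mode,
                    stringsAsFactors = FALSE)
  for (nm in names(x$components)) {
    row[[paste0(nm, "_mm")]] <- unname(x$components[[nm]])
    row[[paste0(nm, "_pct")]] <- unname(x$percent[[nm]])
  }
  row
}

#' Run the full decomposition pipeline on one trial
#'
#' Convenience wrapper: canonicalize the reaching side, low-pass filter
#' (optional), detect the reach window, and dispatch to the task's
#' decomposition.
#'
#' @param trial A [trial_recording()].
#' @param cutoff Low-pass cutoff in Hz, or `NULL` to skip filtering (e.g.
#'   for noise-free synthetic data).
#' @param threshold_fraction Velocity threshold for window detection.
#' @param denominator_mode,min_total Passed to the decomposition.
#' @return A `reach_decomposition`.
#' @export
analyze_trial <- function(trial, cutoff = 6, threshold_fraction = 0.05,
                          denominator_mode = "measured_total", min_total = 20) {
  trial <- mirror_to_canonical_side(trial)
  if (!is.null(cutoff)) trial <- lowpass_filter(trial, cutoff)
  window <- detect_reach_window(trial, threshold_fraction)
  if (trial$task == "forward_reach") {
    decompose_forward_reach(trial, window, denominator_mode, min_total)
  } else {
    decompose_hand_to_mouth(trial, window, denominator_mode, min_total)
  }
}
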