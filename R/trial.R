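# TrialRecording: the central data container.
#
# Coordinate convention (fixed package-wide): positions in millimetres,
# X lateral (+ toward the reaching side after canonicalization),
# Y anterior (+forward), Z vertical (+up). Time in seconds.

#' Construct a trial recording
#'
#' A `trial_recording` holds time-indexed 3D positions (mm) for a subset of
#' the 10-marker set, plus task metadata. Missing samples are explicit `NaN`
#' entries, never dropped.
#'
#' @param positions Named list of numeric matrices, one per marker
#'   (names from [marker_names()]), each `n_frames x 3` with columns X, Y, Z
#'   in mm. All markers must share the same frame count (>= 2).
#' @param sampling_rate Sampling frequency in Hz (> 0; reference protocol 60).
#' @param task `"forward_reach"` or `"hand_to_mouth"`.
#' @param reaching_side `"left"` or `"right"`.
#' @param subject_id Subject identifier.
#' @param upper_extremity_length Optional upper-extremity length in mm
#'   (acromion to fingertip), used by the `arm_length` percent denominator.
#' @param source Free-text provenance of the recording.
#' @param provenance Optional list of processing annotations (filters applied,
#'   interpolated gaps, ...). Maintained by the pipeline functions.
#' @return An object of class `trial_recording`.
#' @examples
#' pos <- list(MP_R = cbind(0, c(200, 250, 300), 0),
#'             TROCHANTER_R = matrix(0, 3, 3))
#' trial_recording(pos, 60, "forward_reach", "right", "demo")
#' @export
trial_recording <- function(positions, sampling_rate, task, reaching_side,
                            subject_id = "unknown",
                            upper_extremity_length = NULL,
                            source = "", provenance = list()) {
  if (!is.list(positions) || length(positions) == 0L || is.null(names(positions))) {
    stop_reachcomp("positions must be a named list of n x 3 matrices",
                   "reachcomp_format_error")
  }
  bad <- setdiff(names(positions), marker_names())
  if (length(bad)) {
    stop_reachcomp(sprintf("unknown marker name(s): %s", paste(bad, collapse = ", ")),
                   "reachcomp_marker_error")
  }
  positions <- lapply(positions, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 3L) {
      stop_reachcomp("each marker matrix must have 3 columns (X, Y, Z)",
                     "reachcomp_format_error")
    }
    colnames(m) <- c("X", "Y", "Z")
    m
  })
  nf <- vapply(positions, nrow, integer(1))
  if (length(unique(nf)) != 1L) {
    stop_reachcomp("all markers must have equal frame counts",
                   "reachcomp_format_error")
  }
  if (nf[[1]] < 2L) {
    stop_reachcomp("trial must have at least 2 frames", "reachcomp_format_error")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop_reachcomp("sampling_rate must be a single positive number",
                   "reachcomp_format_error")
  }
  task <- match.arg(task, c("forward_reach", "hand_to_mouth"))
  reaching_side <- match.arg(reaching_side, c("left", "right"))
  if (!is.null(upper_extremity_length)) {
    stopifnot(is.numeric(upper_extremity_length), upper_extremity_length > 0)
    upper_extremity_length <- as.numeric(upper_extremity_length)
  }
  structure(list(
    positions = positions,
    sampling_rate = as.numeric(sampling_rate),
    task = task,
    reaching_side = reaching_side,
    subject_id = as.character(subject_id),
    upper_extremity_length = upper_extremity_length,
    source = as.character(source),
    provenance = provenance
  ), class = "trial_recording")
}

#' Number of frames in a trial
#' @param trial A [trial_recording()].
#' @return Integer frame count.
#' @export
n_frames <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  nrow(trial$positions[[1]])
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s | %s, %s side | %d markers x %d frames @ %g Hz\n",
              x$subject_id, x$task, x$reaching_side,
              length(x$positions), n_frames(x), x$sampling_rate))
  cat("  markers:", paste(names(x$positions), collapse = ", "), "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a subject record
#'
#' Metadata container for one participant. Fugl-Meyer fields are clinical
#' impairment scores and are only meaningful for the stroke group.
#'
#' @param subject_id Identifier.
#' @param group `"healthy"` or `"stroke"`.
#' @param age Age in years.
#' @param sex Free text (e.g. `"F"`, `"M"`).
#' @param affected_side For stroke subjects, `"left"` or `"right"`.
#' @param fma_total,fma_proximal Optional Fugl-Meyer scores (stroke only).
#' @param upper_extremity_length Upper-extremity length in mm.
#' @return A one-row `data.frame` with class `subject_record`.
#' @export
subject_record <- function(subject_id, group, age = NA_real_, sex = NA_character_,
                           affected_side = NA_character_,
                           fma_total = NA_real_, fma_proximal = NA_real_,
                           upper_extremity_length = NA_real_) {
  group <- match.arg(group, c("healthy", "stroke"))
  if (group == "healthy" && (!is.na(fma_total) || !is.na(fma_proximal))) {
    stop_reachcomp("Fugl-Meyer scores are only admissible for stroke subjects",
                   "reachcomp_format_error")
  }
  out <- data.frame(
    subject_id = as.character(subject_id), group = group,
    age = as.numeric(age), sex = as.character(sex),
    affected_side = as.character(affected_side),
    fma_total = as.numeric(fma_total), fma_proximal = as.numeric(fma_proximal),
    upper_extremity_length = as.numeric(upper_extremity_length),
    stringsAsFactors = FALSE
  )
  class(out) <- c("subject_record", class(out))
  out
}
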