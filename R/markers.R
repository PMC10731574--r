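# Marker vocabulary and task requirements for the simplified 10-marker set.

#' Admissible marker names
#'
#' The simplified marker set covers six anatomical sites, four of them placed
#' bilaterally: mandible (chin), C7 spinous process, acromion, lateral humeral
#' epicondyle, index-finger MP joint and greater trochanter.
#'
#' @return Character vector of the 10 admissible marker names, in canonical
#'   order (used e.g. for trial-table column ordering).
#' @export
marker_names <- function() {
  c("CHIN", "C7",
    "ACROMION_L", "ACROMION_R",
    "EPICONDYLE_L", "EPICONDYLE_R",
    "MP_L", "MP_R",
    "TROCHANTER_L", "TROCHANTER_R")
}

#' @keywords internal
#' @noRd
assert_marker_name <- function(marker) {
  if (!is.character(marker) || length(marker) != 1L ||
      !(marker %in% marker_names())) {
    stop_reachcomp(sprintf("unknown marker name '%s'", paste(marker, collapse = ",")),
                   "reachcomp_marker_error")
  }
  marker
}

# Side-suffixed counterpart of a marker ("MP_R" given side "right").
#' @noRd
sided_marker <- function(base, side) {
  suffix <- if (identical(side, "left")) "_L" else "_R"
  paste0(base, suffix)
}

# Swap _L/_R suffixes (used by mirroring).
#' @noRd
swap_sides <- function(markers) {
  out <- markers
  out[endsWith(markers, "_L")] <- sub("_L$", "_R", markers[endsWith(markers, "_L")])
  out[endsWith(markers, "_R")] <- sub("_R$", "_L", markers[endsWith(markers, "_R")])
  out
}

#' Markers required by a task
#'
#' Forward reach needs the end effector (MP), acromion, C7 and the pelvis
#' reference (greater trochanter), all on the reaching side where sided.
#' Hand-to-mouth additionally needs the humeral epicondyle (for the abduction
#' approximation) and the chin (for cervical flexion).
#'
#' @param task `"forward_reach"` or `"hand_to_mouth"`.
#' @param side Reaching side, `"left"` or `"right"`.
#' @return Character vector of required marker names.
#' @export
required_markers <- function(task = c("forward_reach", "hand_to_mouth"),
                             side = c("right", "left")) {
  task <- match.arg(task)
  side <- match.arg(side)
  base <- c(sided_marker("MP", side), sided_marker("ACROMION", side),
            "C7", sided_marker("TROCHANTER", side))
  if (task == "hand_to_mouth") {
    base <- c(base, sided_marker("EPICONDYLE", side), "CHIN")
  }
  base
}

# Classed error helper: all package errors carry a reachcomp_* condition class.
#' @noRd
stop_reachcomp <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "reachcomp_error", "error", "condition"),
    list(message = message, call = call)
  ))
}
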