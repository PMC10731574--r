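# Trial table dialect: UTF-8, tab-separated, '#key=value' metadata header,
# one row per frame, columns `time` then `<MARKER>_x|_y|_z` in canonical
# marker order. NaN cells are written as the literal `nan`.

TRIAL_META_REQUIRED <- c("task", "side", "sampling_rate")

#' Read a trial table
#'
#' Parses the package's tab-separated trial dialect: leading `#key=value`
#' metadata lines (mandatory keys `task`, `side`, `sampling_rate`), then a
#' header row `time` plus `<marker>_x|_y|_z` columns, then one row per frame.
#' Frame spacing is verified against the declared sampling rate (tolerance
#' 1e-6 s). Short occlusion gaps (`NaN` runs no longer than `max_gap_s`) are
#' linearly interpolated and flagged in the trial's provenance; longer gaps
#' are kept as `NaN` for [validate_marker_set()] to report.
#'
#' @param path Path to a trial table file.
#' @param max_gap_s Maximum gap length (seconds) to interpolate at read time
#'   (default 0.2 s). Set to 0 to disable interpolation.
#' @return A [trial_recording()].
#' @seealso [write_trial_table()]
#' @export
read_trial_table <- function(path, max_gap_s = 0.2) {
  if (!file.exists(path)) {
    stop_reachcomp(sprintf("file not found: %s", path), "reachcomp_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  # metadata must be a contiguous leading block
  meta_lines <- if (length(meta_idx)) lines[meta_idx] else character(0)
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  body <- body[nzchar(body)]

  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  missing_keys <- setdiff(TRIAL_META_REQUIRED, names(meta))
  if (length(missing_keys)) {
    stop_reachcomp(sprintf("missing mandatory metadata key(s): %s",
                           paste0("#", missing_keys, "=", collapse = ", ")),
                   "reachcomp_format_error")
  }
  if (length(body) < 2L) {
    stop_reachcomp("trial table must contain a header row and at least 2 frames",
                   "reachcomp_format_error")
  }

  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  if (header[[1]] != "time") {
    stop_reachcomp("first column must be 'time'", "reachcomp_format_error")
  }
  datacols <- header[-1]
  m <- regmatches(datacols, regexec("^(.*)_([xyz])$", datacols))
  ok <- lengths(m) == 3L
  if (any(!ok)) {
    stop_reachcomp(sprintf("column(s) not of form <marker>_x|_y|_z: %s",
                           paste(datacols[!ok], collapse = ", ")),
                   "reachcomp_format_error")
  }
  col_marker <- vapply(m, `[`, character(1), 2)
  col_axis <- toupper(vapply(m, `[`, character(1), 3))
  if (anyDuplicated(datacols)) {
    stop_reachcomp(sprintf("duplicate marker column(s): %s",
                           paste(unique(datacols[duplicated(datacols)]), collapse = ", ")),
                   "reachcomp_format_error")
  }
  bad <- setdiff(unique(col_marker), marker_names())
  if (length(bad)) {
    stop_reachcomp(sprintf("unknown marker name(s) in header: %s",
                           paste(bad, collapse = ", ")),
                   "reachcomp_marker_error")
  }

  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != length(header))) {
    r <- which(nfield != length(header))[[1]]
    stop_reachcomp(sprintf("row %d has %d fields, expected %d",
                           r, nfield[[r]], length(header)),
                   "reachcomp_format_error")
  }
  cells <- matrix(unlist(rows, use.names = FALSE),
                  nrow = length(rows), byrow = TRUE)
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  # NA from coercion that is not an explicit nan/na marker => parse error
  bad_cell <- which(is.na(vals) & !is.nan(vals) &
                    !tolower(cells) %in% c("nan", "na"), arr.ind = TRUE)
  if (nrow(bad_cell)) {
    stop_reachcomp(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                           cells[bad_cell[1, 1], bad_cell[1, 2]],
                           bad_cell[1, 1], header[bad_cell[1, 2]]),
                   "reachcomp_parse_error")
  }
  vals[is.na(vals)] <- NaN

  rate <- as.numeric(meta$sampling_rate)
  if (is.na(rate) || rate <= 0) {
    stop_reachcomp("metadata sampling_rate must be a positive number",
                   "reachcomp_format_error")
  }
  tm <- vals[, 1]
  if (nrow(vals) > 1 && any(abs(diff(tm) - 1 / rate) > 1e-6)) {
    stop_reachcomp(sprintf("frame spacing inconsistent with sampling_rate=%g Hz (tolerance 1e-6 s)",
                           rate), "reachcomp_format_error")
  }

  markers <- unique(col_marker)
  positions <- lapply(markers, function(mk) {
    out <- matrix(NaN, nrow(vals), 3, dimnames = list(NULL, c("X", "Y", "Z")))
    for (ax in c("X", "Y", "Z")) {
      j <- which(col_marker == mk & col_axis == ax)
      if (length(j) == 1L) out[, ax] <- vals[, j + 1L]
    }
    out
  })
  names(positions) <- markers

  uel <- if (!is.null(meta$upper_extremity_length)) {
    as.numeric(meta$upper_extremity_length)
  } else NULL

  trial <- trial_recording(
    positions = positions, sampling_rate = rate,
    task = meta$task, reaching_side = meta$side,
    subject_id = if (!is.null(meta$subject_id)) meta$subject_id else "unknown",
    upper_extremity_length = uel,
    source = if (!is.null(meta$source)) meta$source else path
  )
  if (max_gap_s > 0) trial <- interpolate_short_gaps(trial, max_gap_s) else trial
}

#' Write a trial table
#'
#' Emits the dialect read by [read_trial_table()], with deterministic column
#' order (`time`, then markers in [marker_names()] order) and fixed numeric
#' formatting, so two writes of the same trial are byte-identical.
#'
#' @param trial A [trial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_reachcomp(sprintf("cannot open '%s' for writing: %s",
                           path, conditionMessage(e)), "reachcomp_io_error")
  })
  on.exit(close(con))
  nf <- n_frames(trial)
  mk <- intersect(marker_names(), names(trial$positions))

  meta <- c(
    sprintf("#task=%s", trial$task),
    sprintf("#side=%s", trial$reaching_side),
    sprintf("#sampling_rate=%s", format(trial$sampling_rate, digits = 15)),
    sprintf("#subject_id=%s", trial$subject_id)
  )
  if (!is.null(trial$upper_extremity_length)) {
    meta <- c(meta, sprintf("#upper_extremity_length=%s",
                            format(trial$upper_extremity_length, digits = 15)))
  }
  if (nzchar(trial$source)) meta <- c(meta, sprintf("#source=%s", trial$source))

  header <- c("time", unlist(lapply(mk, function(m) paste0(m, "_", c("x", "y", "z")))))
  tm <- (seq_len(nf) - 1L) / trial$sampling_rate
  dat <- do.call(cbind, c(list(tm), lapply(mk, function(m) trial$positions[[m]])))
  # %.10f keeps mm-scale positions lossless to < 1e-9 mm; NaN prints as 'nan'
  fmt <- function(x) ifelse(is.nan(x), "nan", sprintf("%.10f", x))
  body <- apply(dat, 1, function(r) paste(fmt(r), collapse = "\t"))
  writeLines(c(meta, paste(header, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}

#' Interpolate short occlusion gaps
#'
#' Linearly interpolates interior `NaN` runs no longer than `max_gap_s` per
#' marker axis; longer runs and runs touching the trial boundary are left as
#' `NaN`. Interpolated spans are recorded in `trial$provenance$interpolated`.
#'
#' @param trial A [trial_recording()].
#' @param max_gap_s Maximum gap duration to fill, seconds.
#' @return The trial with gaps filled.
#' @export
interpolate_short_gaps <- function(trial, max_gap_s = 0.2) {
  stopifnot(inherits(trial, "trial_recording"))
  max_len <- floor(max_gap_s * trial$sampling_rate)
  filled <- character(0)
  for (mk in names(trial$positions)) {
    m <- trial$positions[[mk]]
    for (ax in 1:3) {
      x <- m[, ax]
      if (!anyNA(x)) next
      r <- rle(is.na(x))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        i0 <- starts[[k]]; i1 <- ends[[k]]
        if (i0 == 1L || i1 == length(x)) next          # boundary gap
        if (r$lengths[[k]] > max_len) next             # too long
        x[i0:i1] <- x[i0 - 1L] + (x[i1 + 1L] - x[i0 - 1L]) *
          (seq_len(r$lengths[[k]])) / (r$lengths[[k]] + 1L)
        filled <- c(filled, sprintf("%s.%s[%d:%d]", mk, c("X", "Y", "Z")[ax], i0, i1))
      }
      m[, ax] <- x
    }
    trial$positions[[mk]] <- m
  }
  if (length(filled)) trial$provenance$interpolated <-
      union(trial$provenance$interpolated, filled)
  trial
}

#' Validate the marker set of a trial
#'
#' Checks that every marker required by the trial's task on its reaching side
#' is present with an acceptable fraction of missing (`NaN`) frames.
#' Diagnostics are returned, never raised.
#'
#' @param trial A [trial_recording()].
#' @param max_nan_fraction Maximum tolerated fraction of `NaN` frames per
#'   required marker (default 0.1).
#' @return A `data.frame` with columns `marker`, `problem`, `nan_fraction`;
#'   zero rows iff the trial is analyzable.
#' @export
validate_marker_set <- function(trial, max_nan_fraction = 0.1) {
  stopifnot(inherits(trial, "trial_recording"))
  req <- required_markers(trial$task, trial$reaching_side)
  out <- data.frame(marker = character(0), problem = character(0),
                    nan_fraction = numeric(0), stringsAsFactors = FALSE)
  for (mk in req) {
    if (!mk %in% names(trial$positions)) {
      out <- rbind(out, data.frame(marker = mk, problem = "missing",
                                   nan_fraction = NA_real_))
      next
    }
    frac <- mean(apply(trial$positions[[mk]], 1, anyNA))
    if (frac > max_nan_fraction) {
      out <- rbind(out, data.frame(
        marker = mk,
        problem = sprintf("gap fraction %.1f%% exceeds %.1f%%",
                          100 * frac, 100 * max_nan_fraction),
        nan_fraction = frac))
    }
  }
  out
}
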