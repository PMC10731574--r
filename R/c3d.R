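# Minimal C3D support. The standard motion-capture interchange format is
# binary; no reader exists in the installed R stack, so a compact one is
# implemented here with readBin. Scope: little-endian (Intel) files with
# floating-point point data — the output of essentially every modern
# pipeline. Integer-scaled or DEC/MIPS files raise an explicit error.

#' Ingest a C3D motion-capture file
#'
#' Reads 3D point data from a C3D file, maps its point labels onto the
#' package marker vocabulary, converts units to millimetres and permutes
#' axes into the package convention (X lateral, Y forward, Z up).
#'
#' @param path Path to a C3D file (little-endian, float point data).
#' @param marker_map Named character vector mapping C3D point labels to
#'   [marker_names()], e.g. `c(RFIN = "MP_R", RSHO = "ACROMION_R")`.
#' @param task,reaching_side Trial metadata (the C3D container carries
#'   neither).
#' @param axes Axis permutation: named character vector with elements
#'   `lateral`, `forward`, `up`, each a signed source axis (`"+X"`, `"-Y"`,
#'   ...). Default identity.
#' @param subject_id Subject identifier for the resulting trial.
#' @return A [trial_recording()]; positions in mm, package axis convention,
#'   sampling rate taken from the file.
#' @export
ingest_c3d <- function(path, marker_map,
                       task = c("forward_reach", "hand_to_mouth"),
                       reaching_side = c("right", "left"),
                       axes = c(lateral = "+X", forward = "+Y", up = "+Z"),
                       subject_id = "unknown") {
  task <- match.arg(task)
  reaching_side <- match.arg(reaching_side)
  raw <- read_c3d(path)

  if (!all(c("lateral", "forward", "up") %in% names(axes))) {
    stop_reachcomp("axes must name lateral, forward and up", "reachcomp_format_error")
  }
  unit <- tolower(trimws(raw$units))
  scale <- switch(unit, mm = 1, m = 1000, cm = 10,
                  stop_reachcomp(sprintf("unsupported POINT:UNITS '%s'", raw$units),
                                 "reachcomp_unit_error"))

  labels <- raw$labels
  mapped <- marker_map[labels]
  names(mapped) <- labels
  mapped <- mapped[!is.na(mapped)]
  req <- required_markers(task, reaching_side)
  missing <- setdiff(req, unname(mapped))
  if (length(missing)) {
    stop_reachcomp(sprintf(
      "marker_map does not cover required marker(s) %s; C3D labels present: %s",
      paste(missing, collapse = ", "), paste(labels, collapse = ", ")),
      "reachcomp_mapping_error")
  }

  perm <- lapply(axes, function(a) {
    sgn <- if (startsWith(a, "-")) -1 else 1
    ax <- toupper(sub("^[+-]?", "", a))
    if (!ax %in% c("X", "Y", "Z")) {
      stop_reachcomp(sprintf("bad axis spec '%s'", a), "reachcomp_format_error")
    }
    list(col = match(ax, c("X", "Y", "Z")), sgn = sgn)
  })

  positions <- list()
  for (lab in names(mapped)) {
    src <- raw$points[[match(lab, labels)]] * scale
    out <- cbind(
      X = perm$lateral$sgn * src[, perm$lateral$col],
      Y = perm$forward$sgn * src[, perm$forward$col],
      Z = perm$up$sgn * src[, perm$up$col]
    )
    positions[[mapped[[lab]]]] <- out
  }

  trial_recording(positions, raw$rate, task, reaching_side,
                  subject_id = subject_id, source = path,
                  provenance = list(c3d = basename(path), units = unit))
}

# Low-level C3D parse. Returns list(points = list of n x 3 matrices,
# labels, rate, units).
#' @noRd
read_c3d <- function(path) {
  if (!file.exists(path)) {
    stop_reachcomp(sprintf("file not found: %s", path), "reachcomp_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rdU8 <- function(n = 1) readBin(con, "integer", n, size = 1, signed = FALSE)
  rdI8 <- function(n = 1) readBin(con, "integer", n, size = 1, signed = TRUE)
  rdI16 <- function(n = 1) readBin(con, "integer", n, size = 2, endian = "little")
  rdF32 <- function(n = 1) readBin(con, "double", n, size = 4, endian = "little")

  param_block <- rdU8()
  magic <- rdU8()
  if (magic != 0x50) {
    stop_reachcomp("not a C3D file (bad magic byte)", "reachcomp_format_error")
  }
  npoints <- rdI16()
  rdI16()                      # analog channels per frame (ignored)
  first_frame <- rdI16()
  last_frame <- rdI16()
  rdI16()                      # max interpolation gap
  scale <- rdF32()
  data_block <- rdI16()
  rdI16()                      # analog samples per frame
  rate <- rdF32()
  if (scale >= 0) {
    stop_reachcomp("integer-scaled C3D point data is not supported (float only)",
                   "reachcomp_format_error")
  }

  # --- parameter section ---
  seek(con, (param_block - 1) * 512)
  rdU8(2)
  rdU8()                       # declared parameter block count (unused)
  proc <- rdU8()
  if (proc != 84) {
    stop_reachcomp(sprintf("unsupported C3D processor type %d (Intel/84 only)", proc),
                   "reachcomp_format_error")
  }
  params <- list()
  repeat {
    nchar_name <- rdI8()
    if (length(nchar_name) == 0L || nchar_name == 0L) break
    gid <- rdI8()
    nm <- rawToChar(readBin(con, "raw", abs(nchar_name)))
    offset_pos <- seek(con)    # position of the 2-byte offset word
    offset <- rdI16()
    if (gid < 0) {
      # group definition record
      params[[paste0("G", -gid)]] <- nm
    } else {
      type <- rdI8()
      ndim <- rdI8()
      dims <- if (ndim > 0) rdU8(ndim) else integer(0)
      nel <- if (ndim > 0) prod(dims) else 1L
      val <- switch(as.character(type),
        `-1` = rawToChar(readBin(con, "raw", nel)),
        `1`  = rdI8(nel),
        `2`  = rdI16(nel),
        `4`  = rdF32(nel),
        stop_reachcomp(sprintf("unsupported parameter type %d", type),
                       "reachcomp_format_error"))
      gname <- params[[paste0("G", gid)]]
      if (is.null(gname)) gname <- paste0("G", gid)
      params[[paste0(gname, ":", nm)]] <- list(value = val, dims = dims, type = type)
    }
    if (offset == 0L) break
    # offset is measured from the start of the offset word
    seek(con, offset_pos + offset)
  }

  getp <- function(key) {
    if (is.null(params[[key]])) {
      stop_reachcomp(sprintf("C3D parameter %s missing", key), "reachcomp_format_error")
    }
    params[[key]]
  }
  lab <- getp("POINT:LABELS")
  width <- lab$dims[[1]]
  nlab <- if (length(lab$dims) > 1) lab$dims[[2]] else 1L
  labels <- trimws(substring(lab$value,
                             (seq_len(nlab) - 1) * width + 1,
                             seq_len(nlab) * width))
  units <- trimws(getp("POINT:UNITS")$value)
  prate <- getp("POINT:RATE")$value[[1]]
  if (!is.null(params[["POINT:RATE"]])) rate <- prate

  nframes <- last_frame - first_frame + 1L
  seek(con, (data_block - 1) * 512)
  dat <- rdF32(nframes * npoints * 4L)
  dat <- array(dat, dim = c(4L, npoints, nframes))
  points <- lapply(seq_len(npoints), function(p) {
    m <- t(dat[1:3, p, ])
    colnames(m) <- c("X", "Y", "Z")
    # residual < 0 flags an invalid (unreconstructed) sample
    m[dat[4, p, ] < 0, ] <- NaN
    m
  })
  names(points) <- labels[seq_len(npoints)]
  list(points = points, labels = labels[seq_len(npoints)],
       rate = rate, units = units)
}

# Internal C3D writer: produces a little-endian float-data C3D. Exists so the
# test suite can build binary fixtures programmatically (the repository ships
# no binary files); not part of the public API.
#' @noRd
write_c3d_minimal <- function(points, path, rate = 60, units = "mm") {
  stopifnot(is.list(points), length(points) >= 1, !is.null(names(points)))
  npoints <- length(points)
  nframes <- nrow(points[[1]])
  labels <- names(points)
  width <- max(4L, max(nchar(labels)))
  labpad <- vapply(labels, function(l) formatC(l, width = -width), character(1))

  con <- file(path, "wb")
  on.exit(close(con))
  wU8 <- function(x) writeBin(as.integer(x), con, size = 1)
  wI16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wF32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  pad_to <- function(n) {
    cur <- seek(con)
    if (cur < n) writeBin(raw(n - cur), con)
  }

  # header block
  wU8(2); wU8(0x50)
  wI16(npoints); wI16(0); wI16(1); wI16(nframes); wI16(0)
  wF32(-1)                         # POINT:SCALE < 0 => float data
  wI16(3)                          # data starts at block 3
  wI16(0)
  wF32(rate)
  pad_to(512)

  # parameter section (one block)
  wU8(c(1, 0x50)); wU8(1); wU8(84)
  wgroup <- function(id, name) {
    wU8(nchar(name)); writeBin(as.integer(-id), con, size = 1)
    writeBin(charToRaw(name), con)
    wI16(3)                        # offset: desc-len byte + empty desc => next
    wU8(0)
  }
  wparam <- function(gid, name, type, dims, payload_writer, payload_bytes) {
    wU8(nchar(name)); writeBin(as.integer(gid), con, size = 1)
    writeBin(charToRaw(name), con)
    # offset (from start of this int16): word itself + type + ndim + dims +
    # data + description length byte
    wI16(2 + 1 + 1 + length(dims) + payload_bytes + 1)
    writeBin(as.integer(type), con, size = 1)
    wU8(length(dims)); if (length(dims)) wU8(dims)
    payload_writer()
    wU8(0)                         # empty description
  }
  wgroup(1, "POINT")
  wparam(1, "USED", 2, integer(0), function() wI16(npoints), 2)
  wparam(1, "FRAMES", 2, integer(0), function() wI16(nframes), 2)
  wparam(1, "RATE", 4, integer(0), function() wF32(rate), 4)
  wparam(1, "SCALE", 4, integer(0), function() wF32(-1), 4)
  wparam(1, "UNITS", -1, nchar(units), function() writeBin(charToRaw(units), con),
         nchar(units))
  wparam(1, "LABELS", -1, c(width, npoints),
         function() writeBin(charToRaw(paste(labpad, collapse = "")), con),
         width * npoints)
  wU8(0)                           # terminator record
  pad_to(1024)

  # data section: frames x points x (x,y,z,residual) float32
  for (f in seq_len(nframes)) {
    for (p in seq_len(npoints)) {
      xyz <- points[[p]][f, ]
      res <- if (anyNA(xyz)) -1 else 0
      if (anyNA(xyz)) xyz <- c(0, 0, 0)
      wF32(c(xyz, res))
    }
  }
  invisible(path)
}
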