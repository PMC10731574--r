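# Zero-phase Butterworth low-pass filtering. Implemented from first
# principles (bilinear transform + forward-backward pass with odd extension
# and steady-state initial conditions) because no DSP package is available
# in the dependency set. The frequency response is checked analytically in
# the test suite.

# Polynomial from roots, complex-safe; returns coefficients highest order
# first, leading coefficient 1.
#' @noRd
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0) - c(0, rt * p)
  p
}

# Butterworth low-pass design, order n, cutoff fc Hz at sampling rate fs Hz.
# Returns list(b, a) for the difference equation a[1] y_t = sum b x - sum a y.
#' @noRd
butter_lowpass <- function(n, fc, fs) {
  if (fc <= 0 || fc >= fs / 2) {
    stop_reachcomp(sprintf("cutoff must lie in (0, Nyquist=%g) Hz", fs / 2),
                   "reachcomp_parameter_error")
  }
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warped <- 2 * fs * tan(pi * fc / fs)   # prewarped analog cutoff (rad/s)
  p <- p * warped
  # bilinear transform
  z <- (2 * fs + p) / (2 * fs - p)
  a <- Re(poly_from_roots(z))
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))
  # unit gain at DC
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

# Steady-state initial filter state for a unit step (scipy lfilter_zi).
#' @noRd
lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -a[-1]
  if (n > 2L) A[cbind(1:(n - 2), 2:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - A, B)
}

# Direct-form II transposed IIR filter on the columns of matrix x, with
# per-column initial state zi (length(a)-1 rows).
#' @noRd
lfilter_mat <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  nst <- length(a) - 1L
  z <- if (is.null(zi)) matrix(0, nst, ncol(x)) else zi
  y <- x * 0
  for (t in seq_len(nrow(x))) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (nst > 1L) {
      z[1:(nst - 1), ] <- z[2:nst, , drop = FALSE] +
        outer(b[2:nst], xt) - outer(a[2:nst], yt)
    }
    z[nst, ] <- b[nst + 1L] * xt - a[nst + 1L] * yt
    y[t, ] <- yt
  }
  y
}

# Zero-phase forward-backward filtering with odd extension at both ends and
# steady-state initial conditions (matches scipy.signal.filtfilt defaults).
#' @noRd
filtfilt_mat <- function(b, a, x) {
  x <- as.matrix(x)
  nx <- nrow(x)
  padlen <- min(3L * max(length(a), length(b)), nx - 1L)
  zi <- lfilter_zi(b, a)
  one_pass <- function(xx) {
    z0 <- outer(zi, xx[1, ])
    lfilter_mat(b, a, xx, z0)
  }
  if (padlen > 0L) {
    front <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
      x[(padlen + 1L):2, , drop = FALSE]
    back <- 2 * matrix(x[nx, ], padlen, ncol(x), byrow = TRUE) -
      x[(nx - 1L):(nx - padlen), , drop = FALSE]
    ext <- rbind(front, x, back)
  } else {
    ext <- x
  }
  y <- one_pass(ext)
  y <- one_pass(y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  if (padlen > 0L) y <- y[(padlen + 1L):(padlen + nx), , drop = FALSE]
  y
}

#' Low-pass filter a trial
#'
#' Applies a zero-phase Butterworth low-pass filter (forward-backward pass,
#' so no phase lag) to every marker axis. `NaN` spans are preserved: each
#' contiguous finite run is filtered independently and missing samples stay
#' missing. The applied cutoff is recorded in the trial's provenance.
#'
#' @param trial A [trial_recording()].
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist. The default
#'   6 Hz is the conventional choice for reaching kinematics captured at
#'   60 Hz.
#' @param order Filter order of each pass (default 4).
#' @return Filtered copy of the trial.
#' @export
lowpass_filter <- function(trial, cutoff = 6, order = 4) {
  stopifnot(inherits(trial, "trial_recording"))
  if (cutoff >= trial$sampling_rate / 2) {
    stop_reachcomp(sprintf("cutoff %g Hz is not below Nyquist (%g Hz)",
                           cutoff, trial$sampling_rate / 2),
                   "reachcomp_parameter_error")
  }
  ba <- butter_lowpass(order, cutoff, trial$sampling_rate)
  # batch all marker axes into one matrix so the time loop runs once
  mk_names <- names(trial$positions)
  big <- do.call(cbind, trial$positions)
  has_nan <- apply(big, 2, anyNA)
  if (any(!has_nan)) {
    big[, !has_nan] <- filtfilt_mat(ba$b, ba$a, big[, !has_nan, drop = FALSE])
  }
  for (j in which(has_nan)) {
    x <- big[, j]
    r <- rle(!is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[[k]]:ends[[k]]
      if (length(idx) < 2L) next   # too short to filter; leave as-is
      x[idx] <- filtfilt_mat(ba$b, ba$a, matrix(x[idx]))
    }
    big[, j] <- x
  }
  for (i in seq_along(mk_names)) {
    m <- big[, (3 * i - 2):(3 * i), drop = FALSE]
    colnames(m) <- c("X", "Y", "Z")
    trial$positions[[mk_names[i]]] <- m
  }
  trial$provenance$lowpass <- list(cutoff = cutoff, order = order,
                                   design = "butterworth zero-phase")
  trial
}
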