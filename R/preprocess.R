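#' Drop initial frames from a BOLD series
#'
#' Discards the first `n_drop` volumes (scanner equilibration frames). The
#' caller is responsible for trimming the motion-parameter table
#' identically; [compute_fd()] and [regress_nuisance()] check row counts.
#'
#' @param series a [bold_series()].
#' @param n_drop non-negative integer, strictly less than the frame count.
#' @return the trimmed `bold_series`.
#' @export
drop_initial_frames <- function(series, n_drop = 4L) {
  stopifnot(inherits(series, "bold_series"))
  n_drop <- as.integer(n_drop)
  nt <- n_frames(series)
  if (n_drop < 0L) abort("`n_drop` must be non-negative.")
  if (n_drop >= nt)
    abort(sprintf("cannot drop %d of %d frames.", n_drop, nt))
  if (n_drop == 0L) return(series)
  series$data <- series$data[, , , (n_drop + 1L):nt, drop = FALSE]
  series
}

# Order-4 Butterworth band-pass magnitude response, applied twice
# (forward-backward, zero phase). f in Hz; gain at f = 0 is defined as 0.
butterworth_bandpass_gain <- function(f, low_hz, high_hz, order = 4) {
  f0sq <- low_hz * high_hz
  bw <- high_hz - low_hz
  g <- numeric(length(f))
  nz <- f > 0
  r <- (f[nz]^2 - f0sq) / (f[nz] * bw)
  h2 <- 1 / (1 + r^(2 * order))   # |H(f)|^2 of the single pass
  g[nz] <- h2                      # forward-backward => |H|^2 amplitude gain
  g
}

#' Detrend and band-pass filter a BOLD series
#'
#' Removes each voxel's intercept and linear trend by least squares, then
#' band-pass filters in the frequency domain with the squared magnitude
#' response of an order-4 Butterworth band-pass (the zero-phase,
#' forward-backward convention). Frequencies outside
#' `[low_hz, high_hz]` are attenuated per that response; per-voxel means
#' are ~0 on output.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz pass-band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_seconds)`.
#' @param mask optional 3D logical array; when given, only in-mask voxels
#'   are processed (out-of-mask voxels are zeroed). Purely a speed-up:
#'   in-mask values are identical with or without it.
#' @return the filtered `bold_series`.
#' @export
detrend_bandpass <- function(series, low_hz = 0.01, high_hz = 0.08,
                             mask = NULL) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) abort("need 0 < low_hz < high_hz.")
  if (high_hz >= nyq)
    abort(sprintf("high_hz (%g) must be below Nyquist (%g Hz).", high_hz, nyq))
  voxelwise(series, mask, function(Y, nt) {
    X <- cbind(1, seq_len(nt))
    Y <- Y - X %*% qr.coef(qr(X), Y)   # detrend: residuals on [1, t]
    fft_bandpass(Y, series$tr_seconds, low_hz, high_hz)
  })
}

# Apply fun(Y, nt) to the t x voxels matrix view of a series, optionally
# restricted to in-mask voxels (out-of-mask voxels become 0).
voxelwise <- function(series, mask, fun) {
  d <- dim(series$data)
  nt <- d[4]
  Y <- matrix(series$data, ncol = nt)   # voxels x t
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:3])) abort("mask grid mismatch.")
    keep <- which(as.logical(mask))
    out <- matrix(0, nrow(Y), nt)
    out[keep, ] <- t(fun(t(Y[keep, , drop = FALSE]), nt))
    Y <- out
  } else {
    Y <- t(fun(t(Y), nt))
  }
  series$data <- array(Y, d)
  series
}

# Zero-phase band-pass of the columns of a t x k matrix: multiply the DFT
# by the order-4 Butterworth squared magnitude response.
fft_bandpass <- function(Y, tr_seconds, low_hz, high_hz) {
  Y <- as.matrix(Y)
  nt <- nrow(Y)
  freqs <- (seq_len(nt %/% 2 + 1) - 1) / (nt * tr_seconds)
  gain_half <- butterworth_bandpass_gain(freqs, low_hz, high_hz)
  gain <- numeric(nt)
  gain[seq_along(gain_half)] <- gain_half
  if (nt > 2) {
    up <- seq.int(2, length(gain_half) - if (nt %% 2 == 0) 1 else 0)
    gain[nt + 2 - up] <- gain_half[up]
  }
  Re(stats::mvfft(stats::mvfft(Y) * gain, inverse = TRUE)) / nt
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per-voxel ordinary-least-squares residualization on
#' `[intercept | regressors]` (typically the six rigid-body motion
#' parameters). Residuals are orthogonal to every regressor column.
#'
#' @param series a [bold_series()].
#' @param regressors t x k numeric matrix, full column rank after adding
#'   an intercept.
#' @param mask optional 3D logical array restricting the computation (see
#'   [detrend_bandpass()]).
#' @return the residual `bold_series`.
#' @export
regress_nuisance <- function(series, regressors, mask = NULL) {
  stopifnot(inherits(series, "bold_series"))
  regressors <- as.matrix(regressors)
  nt <- n_frames(series)
  if (nrow(regressors) != nt)
    abort("regressor rows must equal the frame count.")
  if (ncol(regressors) < 1L) abort("need at least one regressor column.")
  X <- cbind(intercept = 1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- setdiff(colnames(X) %||% seq_len(ncol(X)),
                   (colnames(X) %||% seq_len(ncol(X)))[qx$pivot[seq_len(qx$rank)]])
    abort(paste0("nuisance design is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  voxelwise(series, mask, function(Y, nt) qr.resid(qx, Y))
}

#' Framewise displacement from motion parameters
#'
#' Scalar head-motion summary per frame: the sum of absolute frame-to-frame
#' differences of the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a reference sphere:
#' `fd[i] = sum |d trans| + head_radius_mm * sum |d rot|`, with
#' `fd[1] = 0`. Invariant to adding a constant to any motion column.
#'
#' @param motion t x 6 numeric matrix: translations (mm) then rotations
#'   (radians).
#' @param head_radius_mm sphere radius converting radians to mm
#'   (default 50).
#' @return numeric vector of length t, non-negative, first element 0.
#' @export
compute_fd <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) abort("need at least 2 frames to compute FD.")
  if (ncol(motion) != 6L) abort("motion must have 6 columns.")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}
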