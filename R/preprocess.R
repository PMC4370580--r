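#' Per-pixel movie conditioning
#'
#' The conditioning chain applied to every movie before wavefront detection:
#' background subtraction, linear detrending (bleach removal), 2x2 spatial
#' binning, and Savitzky-Golay differentiation, with percent-dF/F conversion
#' available on the un-differentiated branch.
#'
#' @name preprocess
NULL

#' Preprocessing configuration
#'
#' @param baseline_s `c(start, end)` of the baseline (non-epileptiform)
#'   epoch in seconds; default the first 0.5 s.
#' @param savgol_window odd window length in frames (default 11, i.e. 55 ms
#'   at 200 Hz: preserves the >=200 ms event rise while suppressing frame
#'   noise).
#' @param savgol_order polynomial order (default 3).
#' @param bin_factor spatial binning factor (default 2).
#' @return a config list.
#' @export
preprocess_config <- function(baseline_s = c(0, 0.5), savgol_window = 11L,
                              savgol_order = 3L, bin_factor = 2L) {
  if (savgol_window %% 2L != 1L || savgol_window <= savgol_order)
    stop("savgol_window must be odd and greater than savgol_order")
  if (diff(baseline_s) <= 0) stop("baseline window must be non-empty")
  list(baseline_s = baseline_s, savgol_window = as.integer(savgol_window),
       savgol_order = as.integer(savgol_order),
       bin_factor = as.integer(bin_factor))
}

#' Background subtraction
#'
#' Subtracts each pixel's mean over the baseline window, so the baseline
#' epoch of the output has per-pixel mean ~0.
#'
#' @param movie a `vsd_movie`.
#' @param baseline_s baseline window `c(start, end)` in seconds.
#' @return a `vsd_movie`.
#' @export
background_subtract <- function(movie, baseline_s = c(0, 0.5)) {
  idx <- window_frames(movie, baseline_s)
  m <- frames_as_matrix(movie$frames)
  f0 <- colMeans(m[idx, , drop = FALSE])
  m <- sweep(m, 2L, f0, "-")
  d <- dim(movie$frames)
  vsd_movie(matrix_as_frames(m, d[2L], d[3L]), movie$frame_rate,
            movie$pixel_pitch)
}

#' Linear detrending
#'
#' Fits a straight line per pixel over the baseline window and subtracts its
#' extrapolation across the whole movie; removes slow photobleaching drift.
#'
#' @inheritParams background_subtract
#' @return a `vsd_movie`.
#' @export
detrend <- function(movie, baseline_s = c(0, 0.5)) {
  idx <- window_frames(movie, baseline_s)
  t <- movie_times(movie)
  m <- frames_as_matrix(movie$frames)
  X <- cbind(1, t[idx])
  beta <- solve(crossprod(X), crossprod(X, m[idx, , drop = FALSE]))  # 2 x P
  trend <- cbind(1, t) %*% beta
  d <- dim(movie$frames)
  vsd_movie(matrix_as_frames(m - trend, d[2L], d[3L]), movie$frame_rate,
            movie$pixel_pitch)
}

#' Spatial binning
#'
#' Non-overlapping `factor x factor` block means ("post-filtering at 2x2
#' pixels"); trailing rows/columns that do not fill a block are dropped.
#' The pixel pitch scales by `factor`.
#'
#' @param movie a `vsd_movie`.
#' @param factor integer bin factor; 1 is the identity.
#' @return a `vsd_movie` with H,W = floor(H/f), floor(W/f).
#' @export
spatial_bin <- function(movie, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("bin factor must be >= 1")
  if (factor == 1L) return(movie)
  d <- dim(movie$frames)
  h <- (d[2L] %/% factor) * factor; w <- (d[3L] %/% factor) * factor
  hb <- h %/% factor; wb <- w %/% factor
  out <- array(0, c(d[1L], hb, wb))
  for (i in seq_len(factor)) {
    ri <- seq(i, h, by = factor)
    for (j in seq_len(factor)) {
      cj <- seq(j, w, by = factor)
      out <- out + movie$frames[, ri, cj, drop = FALSE]
    }
  }
  vsd_movie(out / factor^2, movie$frame_rate, movie$pixel_pitch * factor)
}

# Savitzky-Golay first-derivative of a time x pixel matrix, per-second units.
# Interior samples use the central filter row; the first/last half-windows
# use the corresponding off-centre rows of the SG projection matrix (a
# polynomial fit over the first/last full window evaluated at the edge).
savgol_matrix_deriv <- function(m, window, order, fs) {
  n <- nrow(m)
  if (n < window) stop("movie shorter than the Savitzky-Golay window")
  FS <- signal::sgolay(p = order, n = window, m = 1L, ts = 1 / fs)
  FS <- unclass(FS)
  half <- (window - 1L) %/% 2L
  centre <- FS[half + 1L, ]
  # interior: FIR filtering (stats::filter handles matrices column-wise)
  out <- stats::filter(m, rev(centre), method = "convolution", sides = 2L)
  out <- matrix(out, nrow = n)
  # edges: off-centre rows applied to the first/last window
  out[seq_len(half), ] <- FS[seq_len(half), , drop = FALSE] %*%
    m[seq_len(window), , drop = FALSE]
  out[(n - half + 1L):n, ] <- FS[(half + 2L):window, , drop = FALSE] %*%
    m[(n - window + 1L):n, , drop = FALSE]
  out
}

#' Savitzky-Golay differentiation
#'
#' Local least-squares polynomial first-derivative estimate per sample,
#' scaled to per-second units; edges are handled by the off-centre rows of
#' the SG projection matrix (polynomial fit over the terminal window).
#'
#' @param x a `vsd_movie`, an `lfp_trace`, or a numeric vector (then
#'   `fs` must be given).
#' @param window odd window length, frames/samples.
#' @param order polynomial order (< window).
#' @param fs sampling rate for plain vectors.
#' @return same type as `x`, holding the first derivative in units/s.
#' @export
savgol_differentiate <- function(x, window = 11L, order = 3L, fs = NULL) {
  if (window %% 2L != 1L || window <= order)
    stop("window must be odd and greater than order")
  if (inherits(x, "vsd_movie")) {
    d <- dim(x$frames)
    m <- savgol_matrix_deriv(frames_as_matrix(x$frames), window, order,
                             x$frame_rate)
    return(vsd_movie(matrix_as_frames(m, d[2L], d[3L]), x$frame_rate,
                     x$pixel_pitch))
  }
  if (inherits(x, "lfp_trace")) {
    m <- savgol_matrix_deriv(matrix(x$samples, ncol = 1L), window, order,
                             x$sample_rate)
    return(lfp_trace(drop(m), x$sample_rate, x$channel))
  }
  if (is.null(fs)) stop("fs must be supplied for plain numeric input")
  drop(savgol_matrix_deriv(matrix(x, ncol = 1L), window, order, fs))
}

#' Percent fluorescence change
#'
#' `100 * (F - F0) / F0` with `F0` the per-pixel baseline-window mean.
#'
#' @inheritParams background_subtract
#' @return a `vsd_movie` in %dF/F units.
#' @export
to_dff <- function(movie, baseline_s = c(0, 0.5)) {
  idx <- window_frames(movie, baseline_s)
  m <- frames_as_matrix(movie$frames)
  f0 <- colMeans(m[idx, , drop = FALSE])
  if (any(f0 <= 0))
    stop("invalid baseline: per-pixel baseline mean must be > 0 for dF/F")
  m <- 100 * sweep(sweep(m, 2L, f0, "-"), 2L, f0, "/")
  d <- dim(movie$frames)
  vsd_movie(matrix_as_frames(m, d[2L], d[3L]), movie$frame_rate,
            movie$pixel_pitch)
}

#' Run the full conditioning chain
#'
#' Applies background subtraction, detrending, spatial binning and
#' Savitzky-Golay differentiation (the "filtered" branch), and builds the
#' percent-dF/F branch (binned, then detrended to remove bleach drift)
#' used for onset detection, amplitude and reverberation measurements.
#'
#' @param movie a raw `vsd_movie` (camera counts).
#' @param config a [preprocess_config()].
#' @return list with `dff` (binned, detrended %dF/F movie), `deriv` (binned,
#'   SG-differentiated movie, counts/s), `binned` (binned background-
#'   subtracted, detrended movie), and the `config`.
#' @export
preprocess_movie <- function(movie, config = preprocess_config()) {
  bs <- config$baseline_s
  # block means commute exactly with per-pixel background subtraction and
  # linear detrending, so binning is applied first for speed; the result is
  # identical to subtract -> detrend -> bin.
  binned_raw <- spatial_bin(movie, config$bin_factor)
  binned <- detrend(background_subtract(binned_raw, bs), bs)
  deriv <- savgol_differentiate(binned, config$savgol_window,
                                config$savgol_order)
  dff <- detrend(to_dff(binned_raw, bs), bs)
  list(dff = dff, deriv = deriv, binned = binned, config = config)
}
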