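#' VSD movie container
#'
#' A time-ordered stack of fluorescence frames with sampling metadata.
#' Frames are stored `[t, row, col]` (real-valued in memory; quantised to
#' 16-bit grayscale on disk).  Frame `k` (0-based) has timestamp
#' `k / frame_rate` seconds.
#'
#' @param frames numeric array `T x H x W`.
#' @param frame_rate sampling rate in Hz (default 200).
#' @param pixel_pitch mm per pixel.
#' @return a `vsd_movie`.
#' @export
vsd_movie <- function(frames, frame_rate = 200, pixel_pitch = 0.025) {
  if (length(dim(frames)) != 3L) stop("frames must be a T x H x W array")
  if (dim(frames)[1L] < 1L) stop("movie needs at least one frame")
  stop_if_not_scalar_number(frame_rate, "frame_rate")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_pitch = pixel_pitch),
            class = "vsd_movie")
}

#' @export
print.vsd_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<vsd_movie> %d frames of %d x %d px @ %g Hz (%.2f s), %.3f mm/px\n",
              d[1L], d[2L], d[3L], x$frame_rate, d[1L] / x$frame_rate,
              x$pixel_pitch))
  invisible(x)
}

#' @export
dim.vsd_movie <- function(x) dim(x$frames)

# frame timestamps in seconds
movie_times <- function(movie) {
  (seq_len(dim(movie$frames)[1L]) - 1L) / movie$frame_rate
}

# convert a half-open window [start, end) in seconds to frame indices
# (1-based); a 0.5 s baseline at 200 Hz is exactly frames 1..100
window_frames <- function(movie, window_s) {
  t <- movie_times(movie)
  idx <- which(t >= window_s[1L] & t < window_s[2L])
  if (!length(idx)) stop("window contains no frames")
  idx
}
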