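# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Reproducible stream of child seeds (< 2^31) from a master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Theil-Sen slope: median of all pairwise slopes
#'
#' Robust slope of `y` against `x` as the median of the slopes of all sample
#' pairs with distinct `x`.  Used by [estimate_velocity()]; exposed because it
#' is the velocity-fit primitive of the pipeline.
#'
#' @param x,y numeric vectors of equal length (NA pairs dropped).
#' @return list with `slope`, `intercept` (median residual intercept) and `n`.
#' @export
theil_sen <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("theil_sen() needs at least 2 finite samples")
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  ok <- dx != 0
  if (!any(ok)) stop("theil_sen(): all x values identical")
  slope <- stats::median(dy[ok] / dx[ok])
  list(slope = slope,
       intercept = stats::median(y - slope * x),
       n = n)
}

# Ordinary least-squares slope (config alternative to Theil-Sen).
ols_slope <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  f <- stats::lm.fit(cbind(1, x[keep]), y[keep])
  list(slope = unname(f$coefficients[2L]),
       intercept = unname(f$coefficients[1L]),
       n = sum(keep))
}

# movie frames [T, H, W] -> matrix [T, H*W], pixels in column-major (row fastest)
frames_as_matrix <- function(frames) {
  d <- dim(frames)
  dim(frames) <- c(d[1L], d[2L] * d[3L])
  frames
}

matrix_as_frames <- function(m, h, w) {
  dim(m) <- c(nrow(m), h, w)
  m
}

# First index of each column's first run of >= min_run TRUEs; NA if none.
# `x` is a logical matrix (time x pixels).  Row sweep keeps this vectorised
# across pixels.
first_run_start <- function(x, min_run) {
  n <- nrow(x); p <- ncol(x)
  idx <- rep(NA_integer_, p)
  runlen <- integer(p)
  done <- logical(p)
  for (t in seq_len(n)) {
    runlen <- ifelse(x[t, ], runlen + 1L, 0L)
    hit <- !done & runlen >= min_run
    if (any(hit)) {
      idx[hit] <- t - min_run + 1L
      done <- done | hit
      if (all(done)) break
    }
  }
  idx
}

# column maxima of a matrix without apply() overhead
col_maxs <- function(m) {
  out <- m[1L, ]
  for (t in seq_len(nrow(m))[-1L]) out <- pmax(out, m[t, ])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
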