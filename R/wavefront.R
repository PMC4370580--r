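#' Wavefront detection and propagation kinematics
#'
#' Onset (isochrone) maps are built from positive crossings of a per-pixel
#' threshold set 2 SD above baseline activity, with the crossing time
#' linearly interpolated between the bracketing frames (5 ms frames cannot
#' otherwise resolve 8 ms laminar delays).  Onset maps are projected onto
#' anatomical axis polylines, and velocities are the inverse slope of a
#' robust (Theil-Sen) fit of onset time against axis distance.
#'
#' @name wavefront
NULL

new_onset_map <- function(onset_s, threshold_map, frame_rate, pixel_pitch) {
  structure(list(onset_s = onset_s, threshold_map = threshold_map,
                 frame_rate = frame_rate, pixel_pitch = pixel_pitch),
            class = "onset_map")
}

#' @export
print.onset_map <- function(x, ...) {
  n <- sum(is.finite(x$onset_s))
  cat(sprintf("<onset_map> %d x %d px, %d active (%.1f%%), onsets %.3f-%.3f s\n",
              nrow(x$onset_s), ncol(x$onset_s), n,
              100 * n / length(x$onset_s),
              suppressWarnings(min(x$onset_s, na.rm = TRUE)),
              suppressWarnings(max(x$onset_s, na.rm = TRUE))))
  invisible(x)
}

#' Per-pixel detection threshold map
#'
#' Threshold = per-pixel mean + 2 SD over the baseline (non-epileptiform)
#' window.
#'
#' @param movie a `vsd_movie` (whichever signal branch onsets are detected
#'   on).
#' @param baseline_s baseline window `c(start, end)`, seconds.
#' @param n_sd number of SDs above the baseline mean (default 2).
#' @return numeric H x W matrix.
#' @export
compute_threshold_map <- function(movie, baseline_s = c(0, 0.5), n_sd = 2) {
  idx <- window_frames(movie, baseline_s)
  if (length(idx) < 2L) stop("baseline window must contain at least 2 frames")
  m <- frames_as_matrix(movie$frames)[idx, , drop = FALSE]
  mu <- colMeans(m)
  sdv <- sqrt(colSums(sweep(m, 2L, mu, "-")^2) / (nrow(m) - 1L))
  d <- dim(movie$frames)
  matrix(mu + n_sd * sdv, d[2L], d[3L])
}

# core crossing detector on a time x pixel matrix: first upward crossing of
# per-pixel `level` at/after frame `start_frame` that stays above for
# >= min_above frames; returns interpolated time (s) per pixel, NA if none.
first_crossing_times <- function(m, level, fs, start_frame = 1L,
                                 min_above = 1L) {
  n <- nrow(m)
  sub <- m[start_frame:n, , drop = FALSE]
  above <- sweep(sub, 2L, level, ">")
  idx <- first_run_start(above, min_above)
  out <- rep(NA_real_, ncol(m))
  hit <- which(!is.na(idx) & idx > 1L)          # need a below-level frame before
  if (length(hit)) {
    i2 <- idx[hit] + start_frame - 1L           # first frame above, absolute
    i1 <- i2 - 1L
    v1 <- m[cbind(i1, hit)]
    v2 <- m[cbind(i2, hit)]
    frac <- (level[hit] - v1) / (v2 - v1)
    out[hit] <- (i1 - 1L + frac) / fs
  }
  # a run starting at the very first searched frame has no bracketing frame:
  # report the frame time itself
  at_start <- which(!is.na(idx) & idx == 1L)
  out[at_start] <- (start_frame - 1L) / fs
  out
}

#' Detect per-pixel wavefront onsets
#'
#' Onset = time of the first upward crossing of the detection level,
#' linearly interpolated between the bracketing frames.  The level is the
#' supplied threshold map (baseline mean + 2 SD), optionally floored at
#' `min_rise_frac` of the pixel's own peak so that the crossing always falls
#' on the rising phase and stays interpolable when baseline variance is
#' negligible.  A crossing must stay above level for `min_above_frames`
#' consecutive frames (debounce against chance 2SD exceedances).  Pixels
#' never crossing are absent (NA).
#'
#' @param movie a `vsd_movie` (%dF/F branch by default in the pipeline).
#' @param threshold_map H x W matrix from [compute_threshold_map()].
#' @param search_start_s first time (s) searched; defaults to 0.  The
#'   pipeline passes the end of the baseline window.
#' @param min_above_frames debounce length (default 5 frames = 25 ms).
#' @param min_rise_frac relative floor as a fraction of the pixel peak
#'   (default 0.2; set 0 to disable).
#' @return an `onset_map`.
#' @export
detect_onsets <- function(movie, threshold_map, search_start_s = 0,
                          min_above_frames = 5L, min_rise_frac = 0.2) {
  d <- dim(movie$frames)
  if (!all(dim(threshold_map) == d[2:3]))
    stop("threshold_map shape does not match the movie")
  m <- frames_as_matrix(movie$frames)
  level <- as.vector(threshold_map)
  start_frame <- max(1L, 1L + ceiling(search_start_s * movie$frame_rate))
  if (min_rise_frac > 0) {
    peak <- col_maxs(m[start_frame:nrow(m), , drop = FALSE])
    level <- pmax(level, min_rise_frac * peak)
  }
  ons <- first_crossing_times(m, level, movie$frame_rate, start_frame,
                              as.integer(min_above_frames))
  new_onset_map(matrix(ons, d[2L], d[3L]), threshold_map,
                movie$frame_rate, movie$pixel_pitch)
}

#' Detect second (re-entrant) activations
#'
#' After a first discharge the fluorescence has typically not returned to
#' baseline, so a re-entrant wave does not literally re-cross the baseline
#' threshold.  A second activation is therefore detected as a rise of at
#' least the pixel's detection increment above the running post-onset
#' minimum of its trace, interpolated like a first onset.
#'
#' @param movie the %dF/F `vsd_movie`.
#' @param onset_map first-onset map (pixels without a first onset are
#'   skipped).
#' @param t_start search start, s (typically first onset + a refractory
#'   margin).
#' @param rise rise increment per pixel: H x W matrix or scalar; defaults to
#'   `min_rise_frac` of each pixel's first-event peak.
#' @param min_rise_frac fraction of the pixel peak used when `rise` is NULL.
#' @param min_above_frames debounce, frames.
#' @return H x W matrix of second-onset times (NA where none).
#' @export
detect_second_onsets <- function(movie, onset_map, t_start,
                                 rise = NULL, min_rise_frac = 0.2,
                                 min_above_frames = 5L) {
  d <- dim(movie$frames)
  m <- frames_as_matrix(movie$frames)
  fs <- movie$frame_rate
  n <- nrow(m)
  start_frame <- max(1L, 1L + ceiling(t_start * fs))
  first <- as.vector(onset_map$onset_s)
  out <- rep(NA_real_, length(first))
  cand <- which(is.finite(first) & first < t_start)
  if (length(cand) && start_frame < n) {
    sub <- m[start_frame:n, cand, drop = FALSE]
    if (is.null(rise)) {
      pk <- apply(m[, cand, drop = FALSE], 2L, max)
      rise_v <- min_rise_frac * pk
    } else if (length(rise) == 1L) {
      rise_v <- rep(rise, length(cand))
    } else {
      rise_v <- as.vector(rise)[cand]
    }
    runmin <- apply(sub, 2L, cummin)
    above <- sub > sweep(runmin, 2L, rise_v, "+")
    idx <- first_run_start(above, as.integer(min_above_frames))
    hit <- which(!is.na(idx) & idx > 1L)
    if (length(hit)) {
      i2 <- idx[hit] + start_frame - 1L
      i1 <- i2 - 1L
      cols <- cand[hit]
      lev <- runmin[cbind(idx[hit] - 1L, hit)] + rise_v[hit]
      v1 <- m[cbind(i1, cols)]; v2 <- m[cbind(i2, cols)]
      frac <- pmin(pmax((lev - v1) / (v2 - v1), 0), 1)
      out[cols] <- (i1 - 1L + frac) / fs
    }
  }
  matrix(out, d[2L], d[3L])
}

#' Spatial-consistency cleanup of an onset map
#'
#' Activation maps of propagating waves are spatially smooth, while
#' threshold-crossing artefacts (a pre-onset noise frame riding just above
#' the 2SD level) appear as isolated pixels whose onset deviates sharply
#' from their surroundings.  Pixels whose onset differs from the median of
#' their `(2 radius + 1)^2` neighbourhood by more than `max_dev_s` are
#' marked never-active.
#'
#' @param onset_map an `onset_map` (or plain onset matrix).
#' @param radius_px neighbourhood radius in pixels (default 2).
#' @param max_dev_s maximal tolerated deviation from the neighbourhood
#'   median (default 0.004 s: safely above onset jitter and true
#'   within-neighbourhood gradients, below the one-frame error of a
#'   noise-triggered early crossing).
#' @param min_neighbors minimum finite neighbours an active pixel needs
#'   (isolated activations are treated as artefacts).
#' @return same type as the input, with outlier onsets removed.
#' @export
clean_onset_map <- function(onset_map, radius_px = 2L, max_dev_s = 0.004,
                            min_neighbors = 5L) {
  ons <- if (inherits(onset_map, "onset_map")) onset_map$onset_s else onset_map
  nb <- neighborhood_median(ons, radius_px)
  bad <- is.finite(ons) &
    (nb$n < min_neighbors | (is.finite(nb$median) &
                               abs(ons - nb$median) > max_dev_s))
  ons[bad] <- NA_real_
  if (inherits(onset_map, "onset_map")) {
    onset_map$onset_s <- ons
    onset_map
  } else ons
}

# median over the (2r+1)^2 - 1 neighbourhood (self excluded) of each pixel,
# NA-aware; also returns the finite-neighbour count
neighborhood_median <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[!(offs$dr == 0L & offs$dc == 0L), ]
  stack <- matrix(NA_real_, h * w, nrow(offs))
  big <- matrix(NA_real_, h + 2L * r, w + 2L * r)
  big[(r + 1L):(r + h), (r + 1L):(r + w)] <- m
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    stack[, k] <- as.vector(big[(r + 1L + dr):(r + h + dr),
                                (r + 1L + dc):(r + w + dc)])
  }
  med <- rep(NA_real_, h * w)
  cnt <- integer(h * w)
  act <- which(is.finite(m))
  if (length(act)) {
    sub <- stack[act, , drop = FALSE]
    cnt[act] <- rowSums(is.finite(sub))
    med[act] <- apply(sub, 1L, stats::median, na.rm = TRUE)
  }
  list(median = matrix(med, h, w), n = matrix(cnt, h, w))
}

#' Project an onset map onto an anatomical axis
#'
#' For each sample point of the axis polyline, takes the earliest finite
#' onset among pixels within `corridor_mm / 2` (Euclidean) of the point.
#' Distance is cumulative along the polyline; no compensation for structure
#' curvature is applied.
#'
#' @param onset_map an `onset_map` (or plain onset matrix with
#'   `pixel_pitch`/`frame_rate` attributes matching the atlas).
#' @param atlas a `region_atlas` on the same grid as the onset map.
#' @param axis_name name of an axis path in the atlas.
#' @param corridor_mm capture corridor width (default 0.2 mm).
#' @return an `axis_profile` data.frame: `distance_mm`, `onset_s`.
#' @export
project_onto_axis <- function(onset_map, atlas, axis_name,
                              corridor_mm = 0.2) {
  ons <- if (inherits(onset_map, "onset_map")) onset_map$onset_s else onset_map
  if (!all(dim(ons) == dim(atlas$label_image)))
    stop("onset map and atlas grids differ")
  path <- atlas$axis_paths[[axis_name]]
  if (is.null(path)) stop(sprintf("atlas has no axis named '%s'", axis_name))
  pitch <- atlas$pixel_pitch
  fin <- which(is.finite(ons))
  if (!length(fin)) {
    prof <- data.frame(distance_mm = path$distance_mm,
                       onset_s = NA_real_)
    class(prof) <- c("axis_profile", class(prof))
    attr(prof, "corridor_mm") <- corridor_mm
    return(prof)
  }
  h <- nrow(ons)
  pr <- ((fin - 1L) %% h)            # 0-based row
  pc <- ((fin - 1L) %/% h)           # 0-based col
  r_half <- (corridor_mm / 2) / pitch
  onset_vals <- ons[fin]
  out <- rep(NA_real_, nrow(path))
  for (k in seq_len(nrow(path))) {
    d2 <- (pr - path$row[k])^2 + (pc - path$col[k])^2
    sel <- d2 <= r_half^2
    if (any(sel)) out[k] <- min(onset_vals[sel])
  }
  prof <- data.frame(distance_mm = path$distance_mm, onset_s = out)
  class(prof) <- c("axis_profile", class(prof))
  attr(prof, "corridor_mm") <- corridor_mm
  prof
}

#' Across-event mean axis profile
#'
#' Averages the onset profiles of several events sample-by-sample (the
#' slope-of-mean-wavefront reading of velocity estimation: per-sample noise
#' shrinks with the number of events).  Profiles must share the same
#' distance grid; samples missing in an event are ignored for that
#' distance.
#'
#' @param profiles list of `axis_profile`s from [project_onto_axis()].
#' @return an `axis_profile` of the mean onsets.
#' @export
mean_axis_profile <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  d <- profiles[[1L]]$distance_mm
  for (p in profiles)
    if (!isTRUE(all.equal(p$distance_mm, d)))
      stop("profiles are on different distance grids")
  m <- vapply(profiles, function(p) p$onset_s, numeric(length(d)))
  out <- data.frame(distance_mm = d,
                    onset_s = rowMeans(m, na.rm = TRUE))
  out$onset_s[is.nan(out$onset_s)] <- NA_real_
  class(out) <- c("axis_profile", class(out))
  out
}

#' Propagation velocity from an axis profile
#'
#' Velocity is the inverse slope of a robust Theil-Sen (median of pairwise
#' slopes) fit of onset time against axis distance, in m/s; the sign gives
#' the direction along the axis.  Ordinary least squares is available via
#' `method = "ols"`.
#'
#' @param profile an `axis_profile`.
#' @param distance_range optional `c(lo, hi)` mm restriction.
#' @param method `"theil_sen"` (default) or `"ols"`.
#' @return list with `velocity_ms` (m/s; `Inf` with `infinite = TRUE` for a
#'   flat profile), `slope_s_per_mm`, `n`, `method`.
#' @export
estimate_velocity <- function(profile, distance_range = NULL,
                              method = c("theil_sen", "ols")) {
  method <- match.arg(method)
  d <- profile$distance_mm; o <- profile$onset_s
  if (!is.null(distance_range)) {
    keep <- d >= distance_range[1L] & d <= distance_range[2L]
    d <- d[keep]; o <- o[keep]
  }
  keep <- is.finite(d) & is.finite(o)
  if (sum(keep) < 4L)
    stop("velocity estimation needs at least 4 finite profile samples")
  fit <- if (method == "theil_sen") theil_sen(d[keep], o[keep])
         else ols_slope(d[keep], o[keep])
  slope <- fit$slope                       # s per mm
  if (slope == 0) {
    return(list(velocity_ms = Inf, infinite = TRUE, slope_s_per_mm = 0,
                n = fit$n, method = method))
  }
  list(velocity_ms = 1e-3 / slope, infinite = FALSE,
       slope_s_per_mm = slope, n = fit$n, method = method)
}

#' Conduction time between two regions
#'
#' Earliest onset in `region_b` minus earliest onset in `region_a`, in ms
#' (negative if `region_b` leads).
#'
#' @param onset_map an `onset_map` or plain onset matrix.
#' @param atlas matching `region_atlas`.
#' @param region_a,region_b region names ([region_mask()] semantics).
#' @return delay in ms.
#' @export
conduction_time <- function(onset_map, atlas, region_a, region_b) {
  ons <- if (inherits(onset_map, "onset_map")) onset_map$onset_s else onset_map
  earliest <- function(region) {
    v <- ons[region_mask(atlas, region)]
    v <- v[is.finite(v)]
    if (!length(v))
      stop(sprintf("region '%s' has no finite onsets", region))
    min(v)
  }
  1000 * (earliest(region_b) - earliest(region_a))
}

#' Detect saltatory jumps along an axis profile
#'
#' A saltation is reported where a distal sample's onset precedes a proximal
#' sample's onset by at least `min_lead_s` across a gap of at least
#' `min_jump_mm` (the signature of a jump to a distal locus followed by
#' back-propagation).  Onsets are median-smoothed before the pair test;
#' qualifying pairs are clustered by their distal locus, and the backfill
#' velocity of each saltation is fitted (Theil-Sen, on raw onsets) over the
#' back-propagating limb only.
#'
#' @param profile an `axis_profile`.
#' @param min_jump_mm minimum jump extent (default 0.2 mm).
#' @param min_lead_s minimum distal lead (default 0.005 s = one frame).
#' @param smooth_k running-median width, samples (default 5).
#' @return data.frame with one row per saltation: `jump_from_mm`,
#'   `jump_to_mm`, `time_s`, `backfill_velocity_ms`.
#' @export
detect_saltation <- function(profile, min_jump_mm = 0.2, min_lead_s = 0.005,
                             smooth_k = 5L) {
  keep <- is.finite(profile$onset_s)
  d <- profile$distance_mm[keep]; o <- profile$onset_s[keep]
  empty <- data.frame(jump_from_mm = numeric(0), jump_to_mm = numeric(0),
                      time_s = numeric(0), backfill_velocity_ms = numeric(0))
  n <- length(d)
  if (n < 4L) return(empty)
  os <- if (n > smooth_k) stats::runmed(o, k = smooth_k) else o
  # future minimum onset (and its locus) over samples at least min_jump distal
  res <- list()
  j_min <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    distal <- which(d - d[i] >= min_jump_mm)
    if (!length(distal)) next
    j <- distal[which.min(os[distal])]
    if (os[i] - os[j] >= min_lead_s) j_min[i] <- j
  }
  qual <- which(!is.na(j_min))
  if (!length(qual)) return(empty)
  # cluster qualifying pairs by distal landing locus
  landing <- d[j_min[qual]]
  ordq <- order(landing)
  qual <- qual[ordq]; landing <- landing[ordq]
  breaks <- c(0L, which(diff(landing) > min_jump_mm), length(landing))
  for (b in seq_len(length(breaks) - 1L)) {
    members <- qual[(breaks[b] + 1L):breaks[b + 1L]]
    to_i <- j_min[members][which.min(os[j_min[members]])]
    from_mm <- min(d[members])
    to_mm <- d[to_i]
    limb <- which(d >= from_mm & d <= to_mm)
    bv <- NA_real_
    if (length(limb) >= 4L) {
      fit <- theil_sen(d[limb], o[limb])
      if (fit$slope < 0) bv <- -1e-3 / fit$slope   # speed of back-propagation
    }
    res[[b]] <- data.frame(jump_from_mm = from_mm, jump_to_mm = to_mm,
                           time_s = o[to_i], backfill_velocity_ms = bv)
  }
  out <- do.call(rbind, res)
  out[order(out$jump_to_mm), , drop = FALSE]
}

#' Peak percent fluorescence change of a region
#'
#' Maximum over time of the region-mean %dF/F trace.
#'
#' @param dff_movie a `vsd_movie` in %dF/F units.
#' @param atlas matching `region_atlas`.
#' @param region region name.
#' @return peak %dF.
#' @export
peak_dff <- function(dff_movie, atlas, region) {
  max(region_mean_trace(dff_movie, atlas, region))
}

#' Region-mean time course
#'
#' @inheritParams peak_dff
#' @return numeric vector, one value per frame.
#' @export
region_mean_trace <- function(dff_movie, atlas, region) {
  mask <- region_mask(atlas, region)
  if (!all(dim(mask) == dim(dff_movie$frames)[2:3]))
    stop("atlas grid does not match the movie")
  m <- frames_as_matrix(dff_movie$frames)
  rowMeans(m[, as.vector(mask), drop = FALSE])
}
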