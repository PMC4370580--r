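#' Event-level measurements and taxonomy
#'
#' Classifies detected events into the four-type taxonomy: Type 1
#' (hippocampal origin, no spread beyond hippocampus), Type 2 (Au1 origin,
#' hippocampus not recruited), Type 3a (hippocampal origin, Au1 recruited,
#' no reverberation), Type 3b (same with reverberation); anything else
#' (e.g. mEC-origin events) is left `unclassified`.
#'
#' @name events
NULL

#' Locate the event origin
#'
#' The origin pixel is the earliest finite onset; ties within one frame
#' interval of the minimum are broken by taking the pixel nearest the
#' centroid of all near-minimal pixels (deterministic).
#'
#' @param onset_map an `onset_map`.
#' @param atlas matching `region_atlas`.
#' @return list with `region`, `xy` (0-based `c(row, col)`), `time_s`.
#' @export
find_origin <- function(onset_map, atlas) {
  ons <- onset_map$onset_s
  if (!any(is.finite(ons))) stop("onset map has no finite onsets")
  t_min <- min(ons, na.rm = TRUE)
  near <- which(is.finite(ons) & ons <= t_min + 1 / onset_map$frame_rate)
  h <- nrow(ons)
  rows <- (near - 1L) %% h
  cols <- (near - 1L) %/% h
  cr <- mean(rows); cc <- mean(cols)
  best <- which.min((rows - cr)^2 + (cols - cc)^2)
  xy <- c(row = rows[best], col = cols[best])
  lab <- atlas$label_image[xy[1L] + 1L, xy[2L] + 1L]
  region <- if (lab == 0L) NA_character_ else unname(atlas$label_names[[as.character(lab)]])
  list(region = region, xy = xy, time_s = ons[near[best]])
}

#' Recruited regions and per-lamina horizontal spread
#'
#' A region counts as recruited when at least `recruit_frac` of its pixels
#' have finite onsets.  Horizontal spread per Au1 lamina is the extent in mm
#' (along the cortical axis, i.e. the column direction) of finite-onset
#' pixels within the lamina mask.
#'
#' @param onset_map an `onset_map`.
#' @param atlas matching `region_atlas`.
#' @param recruit_frac recruitment fraction threshold (default 0.1).
#' @return list with `recruited` (character vector of region names) and
#'   `spread_mm` (named: `Au1_L23`, `Au1_L56`; NA when not recruited).
#' @export
measure_extent <- function(onset_map, atlas, recruit_frac = 0.1) {
  ons <- onset_map$onset_s
  fin <- is.finite(ons)
  recruited <- character(0)
  for (rg in unname(atlas$label_names)) {
    m <- region_mask(atlas, rg)
    if (sum(fin & m) >= recruit_frac * sum(m))
      recruited <- c(recruited, rg)
  }
  spread <- c(Au1_L23 = NA_real_, Au1_L56 = NA_real_)
  for (rg in c("Au1_L23", "Au1_L56")) {
    sel <- fin & region_mask(atlas, rg)
    if (any(sel)) {
      cols <- which(apply(sel, 2L, any)) - 1L
      spread[rg] <- diff(range(cols)) * atlas$pixel_pitch
    }
  }
  list(recruited = recruited, spread_mm = spread)
}

#' Laminar origin within Au1
#'
#' `superficial` if the earliest Au1 onset lies in the layers 2/3 mask,
#' `deep` if in layers 5/6; `n/a` if Au1 is not recruited.
#'
#' @inheritParams measure_extent
#' @return `"superficial"`, `"deep"`, or `"n/a"`.
#' @export
laminar_origin <- function(onset_map, atlas, recruit_frac = 0.1) {
  ons <- onset_map$onset_s
  l23 <- region_mask(atlas, "Au1_L23"); l56 <- region_mask(atlas, "Au1_L56")
  n23 <- sum(is.finite(ons) & l23); n56 <- sum(is.finite(ons) & l56)
  if (n23 < recruit_frac * sum(l23) && n56 < recruit_frac * sum(l56))
    return("n/a")
  e23 <- suppressWarnings(min(ons[l23], na.rm = TRUE))
  e56 <- suppressWarnings(min(ons[l56], na.rm = TRUE))
  if (e23 <= e56) "superficial" else "deep"
}

#' Detect reverberation (re-entrant hippocampal activation)
#'
#' Reverberation is declared when a coherent population of CA1 pixels shows
#' a second activation after the first Au1 onset, with latency inside
#' `window_s`, at a moment when the Au1 region-mean dF/F has not yet decayed
#' to half its initial event maximum.  Latency is the earliest qualifying
#' second CA1 activation minus the first Au1 onset.
#'
#' @param dff_movie %dF/F `vsd_movie` (binned branch).
#' @param onset_map matching first-onset map.
#' @param atlas matching `region_atlas`.
#' @param window_s admissible latency window (default `c(0.3, 1.0)` s,
#'   deliberately wider than the observed 0.42-0.78 s range).
#' @param min_frac minimum fraction of first-activated CA1 pixels that must
#'   re-activate (coherence requirement, default 0.05).
#' @param halfmax_guard_s exclusion margin before the candidate moment when
#'   computing the initial Au1 peak (default 0.1 s).
#' @return list `(reverberates, latency_s)`; `latency_s` is `NA` when FALSE.
#' @export
detect_reverberation <- function(dff_movie, onset_map, atlas,
                                 window_s = c(0.3, 1.0), min_frac = 0.05,
                                 halfmax_guard_s = 0.1) {
  ons <- onset_map$onset_s
  au1 <- region_mask(atlas, "Au1")
  ca1 <- region_mask(atlas, "CA1")
  no <- list(reverberates = FALSE, latency_s = NA_real_)
  au1_on <- ons[au1]; au1_on <- au1_on[is.finite(au1_on)]
  if (!length(au1_on)) return(no)
  t_au1 <- min(au1_on)
  n_first <- sum(is.finite(ons) & ca1)
  if (!n_first) return(no)
  t_lo <- t_au1 + window_s[1L]
  second <- detect_second_onsets(dff_movie, onset_map,
                                 t_start = t_lo)
  second <- clean_onset_map(second)
  sec_ca1 <- second[ca1]
  sec_ca1 <- sec_ca1[is.finite(sec_ca1)]
  sec_ca1 <- sec_ca1[sec_ca1 <= t_au1 + window_s[2L]]
  if (length(sec_ca1) < min_frac * n_first) return(no)
  # robust earliest: the 5th percentile resists residual spurious
  # re-activations that survive the spatial cleanup
  t2 <- stats::quantile(sec_ca1, 0.05, names = FALSE)
  # half-max criterion on the Au1 region-mean dF/F, sampled just before the
  # re-entrant wave departs Au1 so its own re-activation cannot contaminate
  # the measurement of the residual depolarisation
  au1_trace <- region_mean_trace(dff_movie, atlas, "Au1")
  tt <- movie_times(dff_movie)
  t_eval <- max(t_au1 + 0.05, t2 - halfmax_guard_s)
  init_win <- tt >= t_au1 & tt <= t_eval
  if (!any(init_win)) return(no)
  init_peak <- max(au1_trace[init_win])
  now_val <- stats::approx(tt, au1_trace, xout = t_eval, rule = 2)$y
  if (now_val <= init_peak / 2) return(no)
  list(reverberates = TRUE, latency_s = t2 - t_au1)
}

#' Return-wave conduction time from Au1 to CA1
#'
#' Measures the reverberative return wave of a Type 3b event: second
#' activations are detected on the %dF/F traces, spatially cleaned, and the
#' conduction time is the difference of the robust earliest (5th percentile)
#' second activation of CA1 versus Au1, in ms.
#'
#' @inheritParams detect_reverberation
#' @param q robust-earliest quantile (default 0.05).
#' @return delay in ms (positive when CA1 re-activates after Au1).
#' @export
return_conduction_time <- function(dff_movie, onset_map, atlas,
                                   window_s = c(0.3, 1.0), q = 0.05) {
  ons <- onset_map$onset_s
  au1 <- region_mask(atlas, "Au1")
  t_au1 <- suppressWarnings(min(ons[au1], na.rm = TRUE))
  if (!is.finite(t_au1)) stop("region 'Au1' has no finite onsets")
  second <- detect_second_onsets(dff_movie, onset_map,
                                 t_start = t_au1 + window_s[1L])
  second <- clean_onset_map(second)
  robust_min <- function(region) {
    v <- second[region_mask(atlas, region)]
    v <- v[is.finite(v)]
    if (!length(v))
      stop(sprintf("region '%s' shows no second activation", region))
    stats::quantile(v, q, names = FALSE)
  }
  1000 * (robust_min("CA1") - robust_min("Au1"))
}

#' Classify an event from its feature record
#'
#' Pure decision rules over origin and recruitment: hippocampal origin with
#' recruitment confined to hippocampus is Type 1; Au1 origin without
#' hippocampal recruitment is Type 2; hippocampal origin reaching Au1 is
#' Type 3a, or 3b when reverberation is present; anything else (including
#' mEC-origin events) is `unclassified`.
#'
#' @param origin_region region name of the origin pixel.
#' @param recruited character vector of recruited region names.
#' @param reverberates logical.
#' @return `"1"`, `"2"`, `"3a"`, `"3b"` or `"unclassified"`.
#' @export
classify_event <- function(origin_region, recruited, reverberates = FALSE) {
  hip <- hippocampal_labels()
  au1 <- c("Au1_L23", "Au1_L56")
  if (is.null(recruited) || !length(recruited)) return("unclassified")
  if (is.na(origin_region)) return("unclassified")
  origin_hip <- origin_region %in% hip
  origin_au1 <- origin_region %in% au1
  au1_recruited <- any(au1 %in% recruited)
  hip_recruited <- any(hip %in% recruited)
  if (origin_hip && all(recruited %in% hip)) return("1")
  if (origin_au1 && !hip_recruited) return("2")
  if (origin_hip && au1_recruited) return(if (reverberates) "3b" else "3a")
  "unclassified"
}

#' Extract the full feature record of one movie
#'
#' Runs the conditioning chain, detects onsets, and measures origin,
#' recruitment, laminar origin, conduction times, saltations, velocities and
#' reverberation; then classifies the event.
#'
#' @param movie raw `vsd_movie` (camera counts).
#' @param atlas `region_atlas` on the movie's grid.
#' @param config pipeline configuration, see [pipeline_config()].
#' @param keep_movies if TRUE the returned record also carries the binned
#'   %dF/F and derivative movies (large; off by default).
#' @return an `event_record` list; see fields in the implementation and the
#'   event-table schema written by [run_pipeline()].
#' @export
extract_event_features <- function(movie, atlas, config = pipeline_config(),
                                   keep_movies = FALSE) {
  pp <- preprocess_movie(movie, config$preprocess)
  atlas_b <- bin_atlas(atlas, config$preprocess$bin_factor)
  wf <- config$wavefront
  detect_movie <- if (identical(wf$detect_on, "derivative")) pp$deriv else pp$dff
  thr <- compute_threshold_map(detect_movie, config$preprocess$baseline_s)
  om <- detect_onsets(detect_movie, thr,
                      search_start_s = config$preprocess$baseline_s[2L],
                      min_above_frames = wf$min_above_frames,
                      min_rise_frac = wf$min_rise_frac)
  if (isTRUE(wf$clean_map)) om <- clean_onset_map(om)
  origin <- find_origin(om, atlas_b)
  ext <- measure_extent(om, atlas_b, config$events$recruit_frac)
  lam <- laminar_origin(om, atlas_b, config$events$recruit_frac)
  rev <- detect_reverberation(pp$dff, om, atlas_b,
                              window_s = config$events$reverb_window)
  cond <- list()
  pair_list <- list(c("CA1", "Au1_L56"), c("Au1_L23", "Au1_L56"),
                    c("Au1_L56", "Au1_L23"))
  for (pr in pair_list) {
    ok <- all(pr %in% ext$recruited)
    key <- paste(pr, collapse = "->")
    cond[[key]] <- if (ok)
      tryCatch(conduction_time(om, atlas_b, pr[1L], pr[2L]),
               error = function(e) NA_real_) else NA_real_
  }
  prof <- project_onto_axis(om, atlas_b, "periallocortical",
                            wf$corridor_mm)
  salt <- detect_saltation(prof, wf$min_jump_mm, wf$min_lead_s)
  ca_prof <- project_onto_axis(om, atlas_b, "cornu_ammonis", wf$corridor_mm)
  ca1_xr <- tryCatch(region_x_range(atlas_b, "CA1"), error = function(e) NULL)
  vel_ca1 <- tryCatch(
    estimate_velocity(ca_prof, distance_range = ca1_xr,
                      method = wf$velocity_method)$velocity_ms,
    error = function(e) NA_real_)
  peak_origin <- if (!is.na(origin$region))
    peak_dff(pp$dff, atlas_b, origin$region) else NA_real_
  type <- classify_event(origin$region, ext$recruited, rev$reverberates)
  structure(
    list(event_type = type,
         origin_region = origin$region,
         origin_xy = origin$xy,
         origin_time_s = origin$time_s,
         recruited_regions = ext$recruited,
         laminar_origin = c(superficial = "superficial", deep = "deep",
                            `n/a` = "n/a")[[lam]],
         spread_mm = ext$spread_mm,
         conduction_times_ms = cond,
         reverberates = rev$reverberates,
         reverb_latency_s = rev$latency_s,
         saltations = salt,
         velocity_ca1_ms = vel_ca1,
         peak_dff_origin = peak_origin,
         onset_map = om,
         axis_profiles = list(periallocortical = prof,
                              cornu_ammonis = ca_prof),
         dff = if (keep_movies) pp$dff,
         deriv = if (keep_movies) pp$deriv),
    class = "event_record")
}

#' @export
print.event_record <- function(x, ...) {
  cat(sprintf("<event_record> Type %s, origin %s @ (%d,%d) t=%.3fs\n",
              x$event_type, x$origin_region, x$origin_xy[1L], x$origin_xy[2L],
              x$origin_time_s))
  cat("  recruited:", paste(x$recruited_regions, collapse = ", "), "\n")
  cat(sprintf("  laminar origin: %s; reverberates: %s%s\n", x$laminar_origin,
              x$reverberates,
              if (isTRUE(x$reverberates))
                sprintf(" (latency %.3f s)", x$reverb_latency_s) else ""))
  invisible(x)
}
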