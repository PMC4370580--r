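#' Synthetic interictal events with analytic ground truth
#'
#' The generator emulates the kinematics of spontaneous interictal
#' epileptiform events in a disinhibited horizontal hippocampal-neocortical
#' slice as captured by a 200 Hz VSD camera.  Four event types are produced:
#'
#' * **Type 1** - non-propagating hippocampal events: origin at the CA1/CA2
#'   border, slow spread along CA1 (0.17 m/s, ~0.5 mm) and retrograde spread
#'   into CA3 (0.04 m/s).
#' * **Type 2** - non-propagating neocortical events: origin in Au1 layers
#'   2/3, superficial-to-deep conduction of 8 ms, horizontal confinement to
#'   ~1.5 mm.
#' * **Type 3a** - propagating hippocampal events: rapid CA1 spread
#'   (0.37 m/s), saltatory periallocortical transit (jumps to the distal ends
#'   of mEC and lEC followed by 0.47 m/s backfill), a slow perirhinal limb
#'   (0.02 m/s), and "en passant" invasion of deep Au1 at a total
#'   CA1-to-Au1 delay of 25 ms.
#' * **Type 3b** - Type 3a events that also recruit superficial Au1
#'   (deep-to-superficial delay 17 ms) and reverberate: a monotonic return
#'   wave re-invades hippocampus, arriving in CA1 `reverb_latency` seconds
#'   after the first Au1 onset, with an Au1-to-CA1 return conduction time of
#'   74 ms.
#'
#' A fifth label, `"mec"`, generates the rare locally confined
#' mEC-origin events the classifier must leave unclassified.
#'
#' Every pixel's fluorescence is zero until its analytic onset time, then
#' rises exponentially (rise time ~20 ms) and decays with a 0.9 s half-decay,
#' scaled per region to the requested peak percent fluorescence change.  The
#' exact analytic onset time per pixel is returned as ground truth.
#'
#' @name synthetic_events
NULL

#' Paper-default kinematic presets
#'
#' Segment velocities (m/s) and conduction delays (s) used by the default
#' event specs: CA1 0.37 (propagating) / 0.17 (non-propagating), CA3 0.04,
#' periallocortical backfill 0.47, perirhinal 0.02; CA1-to-Au1 total delay
#' 25 ms, Au1-to-CA1 return 74 ms, Au1 L2/3-to-L5 8 ms, L5/6-to-L2/3 17 ms.
#'
#' @return named list of kinematic defaults.
#' @export
kinematic_presets <- function() {
  list(
    v_ca1_propagating = 0.37,   # m/s, CA1 initial spread of Type 3 events
    v_ca1_nonprop     = 0.17,   # m/s, CA1 spread of Type 1 events
    v_ca3             = 0.04,   # m/s, retrograde spread into CA3
    v_subiculum       = 0.15,   # m/s, CA1-subiculum border slowing
    v_backfill        = 0.47,   # m/s, post-jump back-propagation
    v_perirhinal      = 0.02,   # m/s, lEC-to-perirhinal barrier
    v_au1_lateral     = 0.30,   # m/s, horizontal spread within Au1 laminae
    delay_ca1_au1     = 0.025,  # s, CA1 focus to deep Au1
    delay_return      = 0.074,  # s, Au1 to CA1 return conduction
    delay_l23_l5      = 0.008,  # s, Au1 superficial-to-deep (Type 2)
    delay_l56_l23     = 0.017,  # s, Au1 deep-to-superficial (Type 3b)
    jump_arrivals     = c(0.011, 0.018),  # s after origin: distal mEC, lEC
    spread_type1_mm   = 0.5,    # CA1 extent of Type 1 events
    spread_l23_mm     = 1.5,    # Au1 horizontal confinement, layers 2/3
    spread_l56_mm     = 1.6     # Au1 horizontal confinement, layers 5/6
  )
}

# per-type default peak %dF amplitudes (origin region first; paper-anchored)
default_peak_dff <- function(event_type) {
  switch(event_type,
    "1"  = c(CA1 = 0.14, CA3 = 0.10),
    "2"  = c(Au1_L23 = 0.12, Au1_L56 = 0.12),
    "3a" = c(CA1 = 0.16, CA3 = 0.08, subiculum = 0.12, mEC = 0.12,
             lEC = 0.12, perirhinal = 0.10, Au1_L56 = 0.12),
    "3b" = c(CA1 = 0.12, CA3 = 0.08, subiculum = 0.12, mEC = 0.12,
             lEC = 0.12, perirhinal = 0.10, Au1_L56 = 0.12, Au1_L23 = 0.12),
    "mec" = c(mEC = 0.10),
    stop("unknown event type"))
}

default_event_duration <- function(event_type) {
  switch(event_type, "1" = 0.8, "2" = 0.8, "3a" = 1.1, "3b" = 1.9,
         "mec" = 0.8)
}

#' Specify one synthetic interictal event
#'
#' @param event_type `"1"`, `"2"`, `"3a"`, `"3b"` or `"mec"`.
#' @param kinematics named list of velocities/delays; defaults from
#'   [kinematic_presets()], individual entries overridable.
#' @param peak_dff named vector, peak percent fluorescence change per region.
#' @param reverb_latency seconds between the first Au1 onset and the return
#'   wave's arrival in CA1; required for Type 3b, forbidden otherwise.
#' @param reverb_window admissible latency range (default `c(0.42, 0.78)` s).
#' @param event_duration event span in seconds, within `[0.2, 2.8]`.
#' @param origin_time_s onset time of the origin pixel (default 0.6 s,
#'   leaving a 0.5 s baseline epoch plus margin).
#' @param baseline_f mean resting fluorescence in camera counts.
#' @param rise_time_s 0-95% rise time of the fluorescence transient.
#' @param half_decay_s half-decay time of the transient.
#' @param frame_rate camera rate, Hz.
#' @param seed integer; randomness (none in the noiseless movie itself, but
#'   carried for downstream noise injection).
#' @return an `event_spec`.
#' @export
event_spec <- function(event_type = c("1", "2", "3a", "3b", "mec"),
                       kinematics = list(),
                       peak_dff = NULL,
                       reverb_latency = if (identical(event_type, "3b")) 0.6 else NULL,
                       reverb_window = c(0.42, 0.78),
                       event_duration = NULL,
                       origin_time_s = 0.6,
                       baseline_f = 20000,
                       rise_time_s = 0.02,
                       half_decay_s = 0.9,
                       frame_rate = 200,
                       seed = 1L) {
  event_type <- match.arg(event_type)
  kin <- utils::modifyList(kinematic_presets(), kinematics)
  vels <- unlist(kin[startsWith(names(kin), "v_")])
  if (any(vels <= 0)) stop("all velocities must be > 0")
  if (identical(event_type, "3b")) {
    if (is.null(reverb_latency))
      stop("Type 3b events require a reverb_latency")
    if (reverb_latency < reverb_window[1L] || reverb_latency > reverb_window[2L])
      stop(sprintf("reverb_latency must lie in [%g, %g] s",
                   reverb_window[1L], reverb_window[2L]))
  } else if (!is.null(reverb_latency)) {
    stop("reverb_latency is only meaningful for Type 3b events")
  }
  event_duration <- event_duration %||% default_event_duration(event_type)
  if (event_duration < 0.2 || event_duration > 2.8)
    stop("event_duration must lie in [0.2, 2.8] s")
  peak_dff <- peak_dff %||% default_peak_dff(event_type)
  if (any(peak_dff <= 0)) stop("peak_dff values must be > 0")
  structure(
    list(event_type = event_type, kinematics = kin, peak_dff = peak_dff,
         reverb_latency = reverb_latency, event_duration = event_duration,
         origin_time_s = origin_time_s, baseline_f = baseline_f,
         rise_time_s = rise_time_s, half_decay_s = half_decay_s,
         frame_rate = frame_rate, seed = as.integer(seed)),
    class = "event_spec")
}

# physical x-range (mm) of a region in the atlas
region_x_range <- function(atlas, region) {
  m <- region_mask(atlas, region)
  cols <- which(apply(m, 2L, any)) - 1L
  range(cols) * atlas$pixel_pitch
}

# Analytic per-pixel onset times (s), second-event onsets, and peak %dF.
# Returns list(first, second, peak, origin_xy, jump_list).
onset_truth <- function(spec, atlas) {
  for (rg in names(spec$peak_dff))
    region_mask(atlas, rg)          # errors if region absent
  h <- nrow(atlas$label_image); w <- ncol(atlas$label_image)
  pitch <- atlas$pixel_pitch
  x <- matrix(rep((0:(w - 1L)) * pitch, each = h), h, w)  # mm
  kin <- spec$kinematics
  t0 <- spec$origin_time_s
  tt <- function(d_mm, v_ms) d_mm * 1e-3 / v_ms   # travel time in s
  first <- matrix(NA_real_, h, w)
  second <- NULL
  peak <- matrix(NA_real_, h, w)
  set_peak <- function(region) {
    if (!is.na(spec$peak_dff[region])) {
      m <- region_mask(atlas, region) & !is.na(first)
      peak[m] <<- spec$peak_dff[[region]]
    }
  }
  jump_list <- NULL
  type <- spec$event_type

  if (type %in% c("1", "3a", "3b")) {
    ca1 <- region_mask(atlas, "CA1"); ca3 <- region_mask(atlas, "CA3")
    ox <- region_x_range(atlas, "CA1")[1L]           # CA1/CA2 border
    origin_xy <- c(row = 50, col = round(ox / pitch))
    first[ca3] <- t0 + tt(ox - x[ca3], kin$v_ca3)
    if (type == "1") {
      sel <- ca1 & x <= ox + kin$spread_type1_mm
      first[sel] <- t0 + tt(x[sel] - ox, kin$v_ca1_nonprop)
    } else {
      first[ca1] <- t0 + tt(x[ca1] - ox, kin$v_ca1_propagating)
      sub <- region_mask(atlas, "subiculum")
      xr_sub <- region_x_range(atlas, "subiculum")
      t_sub0 <- t0 + tt(xr_sub[1L] - ox, kin$v_ca1_propagating)
      first[sub] <- t_sub0 + tt(x[sub] - xr_sub[1L], kin$v_subiculum)
      # saltatory transit: jumps to the distal ends of mEC then lEC,
      # each followed by backfill toward the subiculum
      xr_mec <- region_x_range(atlas, "mEC")
      xr_lec <- region_x_range(atlas, "lEC")
      t_j <- t0 + kin$jump_arrivals
      mec <- region_mask(atlas, "mEC"); lec <- region_mask(atlas, "lEC")
      first[mec] <- t_j[1L] + tt(xr_mec[2L] - x[mec], kin$v_backfill)
      first[lec] <- t_j[2L] + tt(xr_lec[2L] - x[lec], kin$v_backfill)
      jump_list <- data.frame(
        from_mm = c(xr_mec[1L], xr_lec[1L]),
        to_mm = c(xr_mec[2L], xr_lec[2L]),
        arrival_s = t_j,
        backfill_v = kin$v_backfill)
      prh <- region_mask(atlas, "perirhinal")
      xr_prh <- region_x_range(atlas, "perirhinal")
      first[prh] <- t_j[2L] + tt(x[prh] - xr_prh[1L], kin$v_perirhinal)
      # en passant invasion of deep Au1 at the total CA1->Au1 delay
      l56 <- region_mask(atlas, "Au1_L56")
      xr_au1 <- region_x_range(atlas, "Au1_L56")
      t_au1 <- t0 + kin$delay_ca1_au1
      first[l56] <- t_au1 + tt(x[l56] - xr_au1[1L], kin$v_au1_lateral)
      if (type == "3b") {
        l23 <- region_mask(atlas, "Au1_L23")
        # deep-to-superficial conduction, column-wise
        f56 <- first
        f56[!l56] <- NA_real_
        col56 <- apply(f56, 2L, function(v) suppressWarnings(min(v, na.rm = TRUE)))
        col56[!is.finite(col56)] <- NA_real_
        first[l23] <- rep(col56, each = h)[l23] + kin$delay_l56_l23
        # monotonic return wave: departs proximal deep Au1 74 ms before its
        # CA1 arrival (= first Au1 onset + reverb_latency)
        second <- matrix(NA_real_, h, w)
        t_r0 <- t_au1 + spec$reverb_latency - kin$delay_return
        x_entry <- xr_au1[1L]
        xr_ca1 <- region_x_range(atlas, "CA1")
        v_ret <- (x_entry - xr_ca1[2L]) * 1e-3 / kin$delay_return  # m/s
        ret <- (region_mask(atlas, "CA1") | sub | mec | lec |
                  region_mask(atlas, "perirhinal")) &
          x >= xr_ca1[1L] + 1.0 & x < x_entry
        second[ret] <- t_r0 + tt(x_entry - x[ret], v_ret)
        second[l56] <- t_r0 + tt(x[l56] - x_entry, kin$v_au1_lateral)
      }
    }
  } else if (type == "2") {
    l23 <- region_mask(atlas, "Au1_L23"); l56 <- region_mask(atlas, "Au1_L56")
    xr <- region_x_range(atlas, "Au1_L23")
    cx <- mean(xr)
    origin_xy <- c(row = 25, col = round(cx / pitch))
    s23 <- l23 & abs(x - cx) <= kin$spread_l23_mm / 2
    s56 <- l56 & abs(x - cx) <= kin$spread_l56_mm / 2
    first[s23] <- t0 + tt(abs(x[s23] - cx), kin$v_au1_lateral)
    first[s56] <- t0 + tt(abs(x[s56] - cx), kin$v_au1_lateral) + kin$delay_l23_l5
  } else {  # locally confined mEC-origin event (left unclassified downstream)
    mec <- region_mask(atlas, "mEC")
    xr <- region_x_range(atlas, "mEC")
    cx <- mean(xr)
    origin_xy <- c(row = 75, col = round(cx / pitch))
    sel <- mec & abs(x - cx) <= 0.5
    first[sel] <- t0 + tt(abs(x[sel] - cx), kin$v_au1_lateral)
  }
  for (rg in names(spec$peak_dff)) set_peak(rg)
  # drop pixels with an amplitude-less onset (regions not in peak_dff)
  first[is.na(peak)] <- NA_real_
  if (!is.null(second)) second[is.na(peak)] <- NA_real_
  list(first = first, second = second, peak = peak,
       origin_xy = origin_xy, jump_list = jump_list)
}

# normalised fluorescence transient: 0 before onset, exponential approach to
# 1 with time constant rise_time/3, times a half_decay exponential; scaled so
# its maximum is exactly 1.
transient_waveform <- function(s, rise_time_s, half_decay_s) {
  tau <- rise_time_s / 3
  lam <- log(2) / half_decay_s
  s_peak <- tau * log((1 + tau * lam) / (tau * lam))
  wmax <- (1 - exp(-s_peak / tau)) * exp(-lam * s_peak)
  out <- numeric(length(s))
  pos <- which(s > 0)
  out[pos] <- (1 - exp(-s[pos] / tau)) * exp(-lam * s[pos]) / wmax
  dim(out) <- dim(s)
  out
}

#' Simulate one event movie with analytic ground truth
#'
#' Builds a noiseless VSD movie in which each pixel's fluorescence rises at
#' its analytic onset time (origin time + path distance / segment velocity,
#' with saltatory jumps and, for Type 3b, a reverberative second activation)
#' and returns the exact onset times as ground truth.
#'
#' @param spec an [event_spec()].
#' @param atlas a `region_atlas` containing every region the spec references.
#' @return list with `movie` (a `vsd_movie`, in camera counts), `truth`
#'   (list: `first`/`second` onset matrices in s, `peak` percent-dF matrix,
#'   `origin_xy`, `jump_list`), and `spec`.
#' @export
simulate_event <- function(spec, atlas) {
  truth <- onset_truth(spec, atlas)
  h <- nrow(atlas$label_image); w <- ncol(atlas$label_image)
  n_frames <- round((spec$origin_time_s + spec$event_duration) * spec$frame_rate)
  t <- (0:(n_frames - 1L)) / spec$frame_rate
  active <- which(!is.na(truth$first))
  frames_mat <- matrix(spec$baseline_f, n_frames, h * w)
  if (length(active)) {
    o1 <- truth$first[active]
    amp <- spec$baseline_f * truth$peak[active] / 100   # counts
    o2 <- if (is.null(truth$second)) NULL else truth$second[active]
    tau <- spec$rise_time_s / 3
    lam <- log(2) / spec$half_decay_s
    s_peak <- tau * log((1 + tau * lam) / (tau * lam))
    wmax <- (1 - exp(-s_peak / tau)) * exp(-lam * s_peak)
    wave <- function(s) {           # frame-wise, s is a vector over pixels
      v <- numeric(length(s))
      pos <- s > 0
      sp <- s[pos]
      v[pos] <- (1 - exp(-sp / tau)) * exp(-lam * sp) / wmax
      v
    }
    for (k in seq_len(n_frames)) {
      v <- wave(t[k] - o1)
      if (!is.null(o2)) {
        has2 <- !is.na(o2) & t[k] > o2
        if (any(has2)) v[has2] <- v[has2] + wave(t[k] - o2[has2])
      }
      frames_mat[k, active] <- frames_mat[k, active] + amp * v
    }
  }
  frames <- matrix_as_frames(frames_mat, h, w)
  list(movie = vsd_movie(frames, spec$frame_rate, atlas$pixel_pitch),
       truth = truth, spec = spec)
}

#' Add sensor noise and photobleaching to a movie
#'
#' Additive per-pixel/frame Gaussian noise plus a multiplicative exponential
#' decay trend (laser photobleaching).  Deterministic for a fixed seed.
#'
#' @param movie a `vsd_movie`.
#' @param noise_sd Gaussian noise SD in camera counts (the cohort default,
#'   6.4 counts, is 20% of the peak fluorescence change of the largest
#'   default event on a 20000-count baseline).
#' @param bleach_rate fractional fluorescence loss per second.
#' @param seed integer RNG seed.
#' @return a `vsd_movie`.
#' @export
add_noise_and_bleach <- function(movie, noise_sd = 6.4, bleach_rate = 0.01,
                                 seed = 1L) {
  f <- movie$frames
  if (bleach_rate != 0)
    f <- f * exp(-bleach_rate * movie_times(movie))
  if (noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(f), sd = noise_sd))
  vsd_movie(f, movie$frame_rate, movie$pixel_pitch)
}

#' Specify a cohort of synthetic events
#'
#' @param counts named integer vector: events per ground-truth label.  The
#'   default, `c(type1 = 14, type2 = 11, type3a = 23, type3b = 7, mec = 2)`,
#'   reproduces the observed 57-event composition (the two mEC-origin events
#'   are the ones the classifier must leave unclassified).
#' @param master_seed integer; all per-event seeds derive from it.
#' @param noise_sd,bleach_rate passed to [add_noise_and_bleach()].
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(counts = c(type1 = 14, type2 = 11, type3a = 23,
                                   type3b = 7, mec = 2),
                        master_seed = 7L, noise_sd = 6.4, bleach_rate = 0.01) {
  if (any(counts < 0)) stop("counts must be >= 0")
  known <- c("type1", "type2", "type3a", "type3b", "mec")
  if (!all(names(counts) %in% known))
    stop("counts names must be among: ", paste(known, collapse = ", "))
  structure(list(counts = counts, master_seed = as.integer(master_seed),
                 noise_sd = noise_sd, bleach_rate = bleach_rate),
            class = "cohort_spec")
}

# truncated-normal-ish jitter (clamped at lo) used for cohort variability
rnorm_clamped <- function(n, mean, sd, lo) pmax(stats::rnorm(n, mean, sd), lo)

#' Simulate a cohort of events
#'
#' Draws per-event kinematics around the paper-default presets (velocities
#' and delays jittered with the reported across-event SDs; reverberation
#' latencies uniform on the admissible window; amplitudes with 10% lognormal
#' jitter) and derives per-event seeds reproducibly from the master seed.
#'
#' Movies are large, so by default only the event specs (plus ground-truth
#' labels) are returned and movies are realised on demand with
#' [realize_event()]; `materialize = TRUE` also generates each noisy movie.
#'
#' @param cohort a [cohort_spec()].
#' @param atlas a `region_atlas`.
#' @param materialize logical; if TRUE each element also carries `movie` and
#'   `truth`.
#' @return list of events, each with `spec`, `true_type`, `noise_sd`,
#'   `bleach_rate`, `seed` (and optionally `movie`, `truth`).
#' @export
simulate_cohort <- function(cohort, atlas, materialize = FALSE) {
  type_of <- c(type1 = "1", type2 = "2", type3a = "3a", type3b = "3b",
               mec = "mec")
  labels <- rep(names(cohort$counts), times = cohort$counts)
  n <- length(labels)
  if (n == 0L) return(list())
  seeds <- derive_seeds(cohort$master_seed, n + 1L)
  kin0 <- kinematic_presets()
  events <- with_seed(seeds[n + 1L], {
    lapply(seq_len(n), function(i) {
      ty <- type_of[[labels[i]]]
      kin <- list(
        v_ca1_propagating = rnorm_clamped(1, kin0$v_ca1_propagating, 0.07, 0.1),
        v_ca1_nonprop = rnorm_clamped(1, kin0$v_ca1_nonprop, 0.03, 0.05),
        v_ca3 = rnorm_clamped(1, kin0$v_ca3, 0.01, 0.02),
        v_backfill = rnorm_clamped(1, kin0$v_backfill, 0.11, 0.15),
        delay_ca1_au1 = rnorm_clamped(1, kin0$delay_ca1_au1, 0.008, 0.010),
        delay_return = rnorm_clamped(1, kin0$delay_return, 0.015, 0.030),
        delay_l23_l5 = rnorm_clamped(1, kin0$delay_l23_l5, 0.002, 0.003),
        delay_l56_l23 = rnorm_clamped(1, kin0$delay_l56_l23, 0.003, 0.008))
      peak <- default_peak_dff(ty) * exp(stats::rnorm(1, 0, 0.1))
      lat <- if (ty == "3b") stats::runif(1, 0.42, 0.78) else NULL
      # events are asynchronous to the camera clock: sub-frame origin phase
      t0 <- 0.6 + stats::runif(1, 0, 1 / 200)
      list(spec = event_spec(ty, kinematics = kin, peak_dff = peak,
                             reverb_latency = lat, origin_time_s = t0,
                             seed = seeds[i]),
           true_type = if (ty == "mec") "unclassified" else ty,
           noise_sd = cohort$noise_sd, bleach_rate = cohort$bleach_rate,
           seed = seeds[i])
    })
  })
  if (materialize)
    events <- lapply(events, function(ev) {
      re <- realize_event(ev, atlas)
      c(ev, re[c("movie", "truth")])
    })
  events
}

#' Realise one cohort event as a noisy movie
#'
#' @param event one element of [simulate_cohort()] output.
#' @param atlas a `region_atlas`.
#' @return list with `movie` (noise and bleach applied), `truth`, `spec`.
#' @export
realize_event <- function(event, atlas) {
  sim <- simulate_event(event$spec, atlas)
  movie <- add_noise_and_bleach(sim$movie, event$noise_sd %||% 0,
                                event$bleach_rate %||% 0, event$seed)
  list(movie = movie, truth = sim$truth, spec = sim$spec)
}
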