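#' Synthetic local field potential traces
#'
#' Emulates the pial-surface LFP signature of interictal events and the
#' paired laminar recordings used to measure interlaminar conduction.
#'
#' Pial traces come in two morphologies: *biphasic* (an initial
#' negative-going lobe followed by one positive lobe; the mean+2SD level is
#' crossed exactly twice, spanning 1.17 s by default, peak-to-peak 42 uV) and
#' *triphasic* (initial positive lobe, trough, second positive lobe; four
#' crossings spanning 1.62 s, peak-to-peak 46 uV).  Because the analysis
#' threshold (trace mean + 2SD over the whole epoch) depends on the trace
#' itself, lobe width and gain are calibrated by root-finding against the
#' same measurement chain used downstream (zero-phase 0.5-100 Hz bandpass,
#' then crossing span / peak-to-peak), so the default traces realise the
#' requested span and amplitude by construction.  Default noise is small
#' (0.5 uV) because the traces emulate event-averaged recordings.
#'
#' @name synthetic_lfp
NULL

gauss_lobe <- function(t, center, width, amp) amp * exp(-(t - center)^2 / (2 * width^2))

# Tapered-plateau (Tukey) pulse of duration D starting at t0; taper
# fraction r.  A plateau holds the slow wave above the detection level for
# most of its duration even after zero-phase high-pass filtering.
tukey_lobe <- function(t, t0, D, amp, r = 0.5) {
  s <- (t - t0) / D
  y <- numeric(length(s))
  up <- s > 0 & s < r / 2
  y[up] <- 0.5 * (1 - cos(2 * pi * s[up] / r))
  y[s >= r / 2 & s <= 1 - r / 2] <- 1
  dn <- s > 1 - r / 2 & s < 1
  y[dn] <- 0.5 * (1 - cos(2 * pi * (1 - s[dn]) / r))
  amp * y
}

# Raw (unfiltered, noiseless) pial waveform.  Both morphologies are
# sharp-spike + slow-wave composites: the peak-to-peak amplitude is carried
# by the sharp spike(s) while the threshold-crossing span is set by the
# tapered slow wave, whose duration `par` (s) is calibrated downstream.
#   biphasic : sharp negative spike, then a slow positive wave (the only
#              structure crossing the +2SD level: 2 crossings).
#   triphasic: sharp positive spike, trough, then the slow positive wave
#              (4 crossings: spike up/down, wave up/down).
pial_waveform <- function(t, morphology, par, gain, center = 15) {
  if (morphology == "biphasic") {
    gain * (gauss_lobe(t, center - par / 2 - 0.20, 0.05, -1.0) +
              tukey_lobe(t, center - par / 2, par, 1.17))
  } else {
    gain * (gauss_lobe(t, center, 0.05, 1.0) +
              gauss_lobe(t, center + 0.30, 0.12, -0.83) +
              tukey_lobe(t, center + 0.50, par, 1.0))
  }
}

#' Default pial LFP generator parameters
#'
#' @param morphology `"biphasic"` or `"triphasic"`.
#' @return list of parameters accepted by [simulate_lfp()].
#' @export
lfp_params <- function(morphology = c("biphasic", "triphasic")) {
  morphology <- match.arg(morphology)
  list(
    sample_rate = 2000,
    epoch_s = 30,
    center_s = 15,
    span_s = if (morphology == "biphasic") 1.17 else 1.62,
    p2p_uV = if (morphology == "biphasic") 42 else 46,
    noise_sd_uV = 0.5,
    band_hz = c(0.5, 100)
  )
}

# measurement used during calibration: span of mean+2SD crossings and p2p of
# the bandpassed trace
measure_span_p2p <- function(x, fs, band) {
  xf <- bandpass(lfp_trace(x, fs), band[1L], band[2L])$samples
  lev <- mean(xf) + 2 * stats::sd(xf)
  above <- xf > lev
  idx <- which(diff(above) != 0)
  if (length(idx) < 2L) return(list(span = 0, p2p = max(xf) - min(xf)))
  # linear interpolation of each crossing
  tcross <- (idx - 1 + (lev - xf[idx]) / (xf[idx + 1L] - xf[idx])) / fs
  list(span = max(tcross) - min(tcross), p2p = max(xf) - min(xf))
}

#' Simulate a pial LFP trace of given morphology
#'
#' @param morphology `"biphasic"` or `"triphasic"`.
#' @param params parameter list, see [lfp_params()]; entries override the
#'   defaults for that morphology.
#' @param seed RNG seed for the additive noise.
#' @return an `lfp_trace` (uV samples at `sample_rate`, channel `"pia"`).
#' @export
simulate_lfp <- function(morphology = c("biphasic", "triphasic"),
                         params = list(), seed = 1L) {
  morphology <- match.arg(morphology)
  p <- utils::modifyList(lfp_params(morphology), params)
  fs <- p$sample_rate
  t <- (0:(round(p$epoch_s * fs) - 1L)) / fs
  if (p$p2p_uV == 0) {
    x <- numeric(length(t))
  } else {
    # calibrate gain (post-filter peak-to-peak) and the slow-wave shape
    # parameter (post-filter +2SD crossing span) against the downstream
    # measurement chain; the threshold level couples the two, so iterate.
    gain <- p$p2p_uV / if (morphology == "biphasic") 1.35 else 1.66
    par <- if (morphology == "biphasic") 1.4 * p$span_s else 0.77 * p$span_s
    bounds <- if (morphology == "biphasic")
      c(0.7 * p$span_s, 2.4 * p$span_s) else c(0.3 * p$span_s, 1.2 * p$span_s)
    for (iter in 1:3) {
      m <- measure_span_p2p(pial_waveform(t, morphology, par, gain,
                                          p$center_s), fs, p$band_hz)
      gain <- gain * p$p2p_uV / m$p2p
      f_span <- function(pr) {
        m <- measure_span_p2p(pial_waveform(t, morphology, pr, gain,
                                            p$center_s), fs, p$band_hz)
        m$span - p$span_s
      }
      par <- stats::uniroot(f_span, lower = bounds[1L], upper = bounds[2L],
                            tol = 1e-5)$root
    }
    x <- pial_waveform(t, morphology, par, gain, p$center_s)
  }
  if (p$noise_sd_uV > 0)
    x <- x + with_seed(seed, stats::rnorm(length(x), sd = p$noise_sd_uV))
  lfp_trace(x, fs, channel = "pia")
}

# sharp laminar discharge (uV): fast rise, slower biphasic relaxation;
# onset (first +2SD crossing) is steep so sub-ms delays are measurable
laminar_waveform <- function(t, onset, amp = 200) {
  s <- t - onset
  out <- numeric(length(t))
  pos <- s > 0
  out[pos] <- amp * (exp(-s[pos] / 0.12) - exp(-s[pos] / 0.012)) /
    0.78 - 0.25 * amp * exp(-((s[pos] - 0.35) / 0.15)^2 / 2)
  out
}

#' Simulate a paired laminar LFP recording
#'
#' Two channels (layers 2/3 and 5/6 of Au1) carrying the same sharp
#' interictal discharge offset by an interlaminar conduction delay.
#' `preset = "type2"` reproduces the superficial-to-deep 8 ms conduction of
#' neocortical-origin events (L2/3 leads); `preset = "type3"` the
#' deep-to-superficial 17 ms conduction of hippocampally projected events
#' (L5/6 leads).
#'
#' @param preset `"type2"` or `"type3"`, or `NULL` to use `delay_s`/`leader`.
#' @param delay_s conduction delay in seconds (overrides the preset value).
#' @param leader `"L2/3"` or `"L5/6"`: which channel fires first.
#' @param sample_rate Hz.
#' @param epoch_s epoch length, s.
#' @param onset_s discharge onset of the leading channel, s.
#' @param amp_uV discharge amplitude, uV.
#' @param noise_sd_uV channel noise SD, uV.
#' @param seed RNG seed.
#' @return named list of two `lfp_trace`s: `L2/3` and `L5/6`.
#' @export
simulate_lfp_pair <- function(preset = c("type2", "type3"), delay_s = NULL,
                              leader = NULL, sample_rate = 2000, epoch_s = 6,
                              onset_s = 2, amp_uV = 200, noise_sd_uV = 2,
                              seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    if (is.null(delay_s))
      delay_s <- if (preset == "type2") kinematic_presets()$delay_l23_l5
                 else kinematic_presets()$delay_l56_l23
    if (is.null(leader)) leader <- if (preset == "type2") "L2/3" else "L5/6"
  }
  fs <- sample_rate
  t <- (0:(round(epoch_s * fs) - 1L)) / fs
  onsets <- if (identical(leader, "L2/3"))
    c("L2/3" = onset_s, "L5/6" = onset_s + delay_s)
  else c("L5/6" = onset_s, "L2/3" = onset_s + delay_s)
  seeds <- derive_seeds(seed, 2L)
  traces <- lapply(seq_along(onsets), function(i) {
    x <- laminar_waveform(t, onsets[i], amp_uV)
    if (noise_sd_uV > 0)
      x <- x + with_seed(seeds[i], stats::rnorm(length(x), sd = noise_sd_uV))
    lfp_trace(x, fs, channel = names(onsets)[i])
  })
  names(traces) <- names(onsets)
  traces[c("L2/3", "L5/6")]
}
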