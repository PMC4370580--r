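# Shared fixtures, memoised per test session (full-size synthetic events are
# expensive to build, and several test files interrogate the same ones).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

default_atlas <- function() memo("atlas", function() build_region_atlas())

binned_atlas <- function() memo("atlas_b", function() bin_atlas(default_atlas(), 2L))

default_cfg <- function() memo("cfg", function() pipeline_config())

# block-mean a full-resolution truth matrix down to the binned grid
bin_truth <- function(m, f = 2L) {
  h <- (nrow(m) %/% f) * f; w <- (ncol(m) %/% f) * f
  out <- 0
  for (i in seq_len(f)) for (j in seq_len(f))
    out <- out + m[seq(i, h, f), seq(j, w, f)]
  out / f^2
}

# A full synthetic event analysed end to end; slim components only.
event_fixture <- function(key) {
  memo(paste0("ev_", key), function() {
    atlas <- default_atlas()
    cfg <- default_cfg()
    spec <- switch(key,
      zero3a  = event_spec("3a", seed = 11L),
      noisy3a = event_spec("3a", seed = 42L),
      noisy3b = event_spec("3b", seed = 42L),
      noisy2  = event_spec("2", seed = 21L),
      stop("unknown fixture"))
    sim <- simulate_event(spec, atlas)
    movie <- if (key == "zero3a") sim$movie
             else add_noise_and_bleach(sim$movie, 6.4, 0.01, spec$seed)
    rec <- extract_event_features(movie, atlas, cfg, keep_movies = TRUE)
    list(spec = spec, truth = sim$truth, rec = rec)
  })
}

# small deterministic movie builders ---------------------------------------

flat_movie <- function(value = 100, t = 20, h = 4, w = 4, fs = 200) {
  vsd_movie(array(value, c(t, h, w)), fs, 0.025)
}

ramp_movie <- function(slope = 3, t = 100, h = 3, w = 3, fs = 200) {
  tt <- (0:(t - 1)) / fs
  vsd_movie(array(rep(slope * tt, h * w), c(t, h, w)), fs, 0.025)
}
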