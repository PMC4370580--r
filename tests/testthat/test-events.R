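test_that("origin localisation picks the earliest pixel with deterministic ties", {
  ab <- binned_atlas()
  h <- nrow(ab$label_image); w <- ncol(ab$label_image)
  ons <- matrix(NA_real_, h, w)
  ons[20, 15] <- 0.61; ons[40, 100] <- 0.7
  om <- ictalwave:::new_onset_map(ons, matrix(0, h, w), 200, ab$pixel_pitch)
  o <- find_origin(om, ab)
  expect_equal(unname(o$xy), c(19, 14))
  expect_identical(o$region, "CA1")
  expect_equal(o$time_s, 0.61)
  # two simultaneous pixels: centroid tie-break, stable across calls
  ons2 <- matrix(NA_real_, h, w)
  ons2[20, 15] <- 0.61; ons2[20, 19] <- 0.61
  om2 <- ictalwave:::new_onset_map(ons2, matrix(0, h, w), 200, ab$pixel_pitch)
  o1 <- find_origin(om2, ab); o2 <- find_origin(om2, ab)
  expect_identical(o1, o2)
  expect_true(all(o1$xy == c(19, 14)) || all(o1$xy == c(19, 18)))
  expect_error(find_origin(ictalwave:::new_onset_map(
    matrix(NA_real_, h, w), matrix(0, h, w), 200, ab$pixel_pitch), ab),
    "no finite onsets")
})

test_that("neocortical-origin events are superficial and horizontally confined", {
  fx <- event_fixture("noisy2")
  expect_identical(fx$rec$origin_region, "Au1_L23")
  expect_identical(fx$rec$laminar_origin, "superficial")
  expect_equal(unname(fx$rec$spread_mm["Au1_L23"]), 1.5, tolerance = 0.1)
  expect_false(any(c("CA1", "CA3") %in% fx$rec$recruited_regions))
  expect_equal(fx$rec$conduction_times_ms[["Au1_L23->Au1_L56"]], 8,
               tolerance = 5)
})

test_that("propagating events recruit the whole periallocortical chain", {
  fx <- event_fixture("noisy3a")
  expect_true(all(c("subiculum", "mEC", "lEC", "perirhinal", "Au1_L56") %in%
                    fx$rec$recruited_regions))
  expect_identical(fx$rec$laminar_origin, "deep")
  expect_identical(fx$rec$origin_region, "CA1")
  # empty onset map -> nothing recruited
  ab <- binned_atlas()
  om <- ictalwave:::new_onset_map(
    matrix(NA_real_, nrow(ab$label_image), ncol(ab$label_image)),
    matrix(0, nrow(ab$label_image), ncol(ab$label_image)), 200,
    ab$pixel_pitch)
  expect_length(measure_extent(om, ab)$recruited, 0L)
})

test_that("reverberation detection separates Type 3a from 3b", {
  ab <- binned_atlas()
  fx3a <- event_fixture("noisy3a")
  rv <- detect_reverberation(fx3a$rec$dff, fx3a$rec$onset_map, ab)
  expect_false(rv$reverberates)
  expect_true(is.na(rv$latency_s))
  fx3b <- event_fixture("noisy3b")
  rv <- detect_reverberation(fx3b$rec$dff, fx3b$rec$onset_map, ab)
  expect_true(rv$reverberates)
  expect_equal(rv$latency_s, 0.6, tolerance = 0.02)
})

test_that("re-entry timed right but with a decayed neocortex is not reverberation", {
  # same Type 3b kinematics but a fast-decaying transient: at the re-entry
  # moment the Au1 fluorescence is far below half its initial maximum
  atlas <- default_atlas()
  spec <- event_spec("3b", seed = 9L, half_decay_s = 0.2)
  sim <- simulate_event(spec, atlas)
  rec <- extract_event_features(sim$movie, atlas, default_cfg(),
                                keep_movies = TRUE)
  rv <- detect_reverberation(rec$dff, rec$onset_map, binned_atlas())
  expect_false(rv$reverberates)
})

test_that("classification rules are mutually exclusive with an unclassified catch-all", {
  expect_identical(classify_event("CA1", c("CA1", "CA3")), "1")
  expect_identical(classify_event("Au1_L23", c("Au1_L23", "Au1_L56")), "2")
  expect_identical(
    classify_event("CA1", c("CA1", "subiculum", "mEC", "Au1_L56"), FALSE), "3a")
  expect_identical(
    classify_event("CA1", c("CA1", "subiculum", "mEC", "Au1_L56"), TRUE), "3b")
  expect_identical(classify_event("mEC", c("mEC")), "unclassified")
  expect_identical(classify_event("Au1_L23", c("Au1_L23", "CA1")),
                   "unclassified")
  expect_identical(classify_event("CA1", character(0)), "unclassified")
  expect_identical(classify_event(NA_character_, "CA1"), "unclassified")
  # hippocampal origin reaching only the subiculum: flagged, not guessed
  expect_identical(classify_event("CA1", c("CA1", "subiculum")),
                   "unclassified")
})

test_that("mEC-origin events come out unclassified with their origin flagged", {
  atlas <- default_atlas()
  sim <- simulate_event(event_spec("mec", seed = 13L), atlas)
  mv <- add_noise_and_bleach(sim$movie, 6.4, 0.01, 13L)
  rec <- extract_event_features(mv, atlas, default_cfg())
  expect_identical(rec$event_type, "unclassified")
  expect_identical(rec$origin_region, "mEC")
})
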