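test_that("default atlas has the full region set and a long anatomical axis", {
  atlas <- default_atlas()
  expect_setequal(unname(atlas$label_names),
                  c("CA3", "CA1", "subiculum", "mEC", "lEC", "perirhinal",
                    "Au1_L23", "Au1_L56"))
  expect_gte(max(atlas$axis_paths$hippocampo_neocortical$distance_mm), 5)
  # every pixel has exactly one label or background
  expect_true(all(atlas$label_image %in% 0:8))
})

test_that("overlapping region polygons are rejected", {
  cfg <- default_atlas_config()
  cfg$regions$CA1 <- ictalwave:::rect_region(10L, 30L, 0L, 99L)  # overlaps CA3
  expect_error(build_region_atlas(cfg), "overlap")
})

test_that("axis paths must stay on the grid and accumulate distance correctly", {
  cfg <- default_atlas_config()
  cfg$axes$bad <- rbind(c(50, 430), c(50, 500))
  expect_error(build_region_atlas(cfg), "leaves the pixel grid")
  # right-angle path of two 1 mm legs (40 px at 25 um) spans 2 mm
  cfg <- default_atlas_config()
  cfg$axes <- list(elbow = rbind(c(10, 10), c(10, 50), c(50, 50)))
  a <- build_region_atlas(cfg)
  expect_equal(max(a$axis_paths$elbow$distance_mm), 2, tolerance = 1e-12)
})

test_that("Type 1 events stay inside the hippocampus with analytic onsets", {
  atlas <- default_atlas()
  sim <- simulate_event(event_spec("1", seed = 1L), atlas)
  hip <- region_mask(atlas, "hippocampus")
  expect_true(all(is.na(sim$truth$first[!hip])))
  # analytic oracle: CA1 onset = t0 + distance from the 0.5 mm border / v
  x <- 0.8  # mm, inside the 0.5 mm spread
  col <- round(x / atlas$pixel_pitch) + 1L
  expect_equal(sim$truth$first[40, col],
               0.6 + (x - 0.5) * 1e-3 / 0.17, tolerance = 1e-12)
  # CA3 retrograde leg
  expect_equal(sim$truth$first[40, 5],
               0.6 + (0.5 - 4 * 0.025) * 1e-3 / 0.04, tolerance = 1e-12)
})

test_that("zero-noise movies realise the analytic onsets exactly", {
  atlas <- default_atlas()
  sim <- simulate_event(event_spec("3a", seed = 2L), atlas)
  # fluorescence is exactly baseline until the analytic onset
  px <- c(60, 300)  # an lEC pixel
  o <- sim$truth$first[px[1L], px[2L]]
  tt <- ictalwave:::movie_times(sim$movie)
  before <- sim$movie$frames[tt <= o, px[1L], px[2L]]
  expect_true(all(before == 20000))
  after <- sim$movie$frames[tt > o + 0.01, px[1L], px[2L]]
  expect_true(all(after > 20000))
  # saltatory ground truth: deep Au1 starts exactly 25 ms after the origin
  au1 <- region_mask(atlas, "Au1_L56")
  expect_equal(min(sim$truth$first[au1], na.rm = TRUE) -
                 min(sim$truth$first, na.rm = TRUE), 0.025, tolerance = 1e-9)
})

test_that("Type 3b ground truth places the hippocampal re-entry at the latency", {
  atlas <- default_atlas()
  sim <- simulate_event(event_spec("3b", reverb_latency = 0.5, seed = 3L), atlas)
  hip <- region_mask(atlas, "hippocampus")
  au1 <- region_mask(atlas, "Au1")
  t_au1 <- min(sim$truth$first[au1], na.rm = TRUE)
  t_second <- min(sim$truth$second[hip], na.rm = TRUE)
  expect_equal(t_second - t_au1, 0.5, tolerance = 1e-9)
})

test_that("event specs enforce their invariants", {
  expect_error(event_spec("1", reverb_latency = 0.5), "only meaningful")
  expect_error(event_spec("3b", reverb_latency = 0.2), "must lie in")
  expect_error(event_spec("3a", event_duration = 3.5), "0.2, 2.8")
  expect_error(event_spec("3a", kinematics = list(v_ca3 = -1)), "> 0")
  expect_error(simulate_event(event_spec("1", peak_dff = c(nucleus = 0.2)),
                              default_atlas()),
               "not present")
})

test_that("noise and bleach behave as specified", {
  mv <- flat_movie(1000, t = 40)
  expect_identical(add_noise_and_bleach(mv, 0, 0, 1L)$frames, mv$frames)
  # bleach closed form: frame-t mean = initial x exp(-r t)
  r <- 0.5
  out <- add_noise_and_bleach(mv, 0, r, 1L)
  tt <- ictalwave:::movie_times(mv)
  means <- apply(out$frames, 1L, mean)
  expect_equal(means, 1000 * exp(-r * tt), tolerance = 1e-12)
  # determinism
  a <- add_noise_and_bleach(mv, 2, 0.1, 7L)
  b <- add_noise_and_bleach(mv, 2, 0.1, 7L)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames,
                         add_noise_and_bleach(mv, 2, 0.1, 8L)$frames))
})

test_that("cohorts conserve the requested composition and are reproducible", {
  atlas <- default_atlas()
  coh <- cohort_spec()
  ev <- simulate_cohort(coh, atlas)
  expect_length(ev, 57L)
  types <- vapply(ev, function(e) e$spec$event_type, character(1))
  expect_equal(sum(types == "1"), 14L)
  expect_equal(sum(types == "2"), 11L)
  expect_equal(sum(types == "3a"), 23L)
  expect_equal(sum(types == "3b"), 7L)
  expect_equal(sum(types == "mec"), 2L)
  expect_length(simulate_cohort(cohort_spec(counts = c(type1 = 0)), atlas), 0L)
  ev2 <- simulate_cohort(cohort_spec(), atlas)
  expect_identical(lapply(ev, `[[`, "spec"), lapply(ev2, `[[`, "spec"))
  expect_error(cohort_spec(counts = c(type1 = -1)), ">= 0")
})

test_that("pial LFP polarities and flat-trace degenerate case", {
  bi <- bandpass(simulate_lfp("biphasic", seed = 5L))
  tri <- bandpass(simulate_lfp("triphasic", seed = 5L))
  expect_identical(classify_morphology(bi)$initial_polarity, "negative")
  expect_identical(classify_morphology(tri)$initial_polarity, "positive")
  flat <- simulate_lfp("biphasic", params = list(p2p_uV = 0, noise_sd_uV = 0))
  expect_true(all(flat$samples == 0))
})
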