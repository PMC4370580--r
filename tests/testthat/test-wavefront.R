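test_that("threshold map is baseline mean + 2 SD, matching a two-pass oracle", {
  expect_true(all(compute_threshold_map(flat_movie(7, t = 120)) == 7))
  set.seed(6)
  mv <- vsd_movie(array(rnorm(120 * 16, 10, 3), c(120, 4, 4)), 200, 0.025)
  thr <- compute_threshold_map(mv, c(0, 0.5))
  # independent two-pass oracle
  for (i in 1:4) for (j in 1:4) {
    v <- mv$frames[1:100, i, j]
    mu <- sum(v) / 100
    sdv <- sqrt(sum((v - mu)^2) / 99)
    expect_lt(abs(thr[i, j] - (mu + 2 * sdv)), 1e-9)
  }
  expect_error(compute_threshold_map(mv, c(0, 0.001)), "window")
})

test_that("onset interpolation places a mid-frame crossing at the sub-frame time", {
  # crossing between frames 10 and 11 (0-based) at 200 Hz, fraction 0.5
  f <- array(0, c(30, 2, 2))
  f[12:30, , ] <- 2                       # frame 12 (1-based) = 0-based 11
  mv <- vsd_movie(f, 200, 0.025)
  om <- detect_onsets(mv, matrix(1, 2, 2), min_above_frames = 5L,
                      min_rise_frac = 0)
  expect_equal(unique(as.vector(om$onset_s)), 0.0525, tolerance = 1e-12)
  # always-subthreshold pixels are absent
  f[, 1, 1] <- 0.5
  om <- detect_onsets(vsd_movie(f, 200, 0.025), matrix(1, 2, 2),
                      min_rise_frac = 0)
  expect_true(is.na(om$onset_s[1, 1]))
  expect_false(anyNA(om$onset_s[2, ]))
})

test_that("zero-noise detection matches analytic ground truth within 5 ms", {
  fx <- event_fixture("zero3a")
  truth_b <- bin_truth(fx$truth$first)
  det <- fx$rec$onset_map$onset_s
  both <- is.finite(det) & is.finite(truth_b)
  # coverage: nearly every truly active pixel is detected
  expect_gt(mean(is.finite(det[is.finite(truth_b)])), 0.98)
  expect_lt(max(abs(det[both] - truth_b[both])), 0.005)
})

test_that("axis projection takes the earliest onset within the corridor", {
  ab <- binned_atlas()
  h <- nrow(ab$label_image); w <- ncol(ab$label_image)
  ons <- matrix(NA_real_, h, w)
  ons[38, 60] <- 1.0                       # a single pixel on the axis row
  prof <- project_onto_axis(ons, ab, "hippocampo_neocortical", 0.2)
  hit <- which(is.finite(prof$onset_s))
  expect_gt(length(hit), 0L)
  expect_true(all(abs(prof$distance_mm[hit] - 59 * 0.05) <= 0.13))
  expect_true(all(prof$onset_s[hit] == 1.0))
  # plane wave: onset linear in column -> profile linear in distance
  # (residuals bounded by the per-pixel onset step: corridor capture is
  # quantised to the pixel grid)
  ons <- matrix(rep((0:(w - 1)) * 0.002, each = h), h, w)
  prof <- project_onto_axis(ons, ab, "hippocampo_neocortical", 0.2)
  fit <- lm(onset_s ~ distance_mm, data = prof)
  expect_lt(max(abs(residuals(fit))), 2.5 * 0.002)
  expect_equal(unname(coef(fit)[2L]), 0.002 / 0.05, tolerance = 0.01)
  # brute-force oracle on a random sparse map
  set.seed(7)
  ons <- matrix(NA_real_, h, w)
  idx <- sample(length(ons), 4000)
  ons[idx] <- runif(4000)
  prof <- project_onto_axis(ons, ab, "periallocortical", 0.2)
  path <- ab$axis_paths$periallocortical
  fin <- which(is.finite(ons))
  pr <- (fin - 1) %% h; pc <- (fin - 1) %/% h
  r2 <- (0.1 / ab$pixel_pitch)^2
  for (k in c(1, 57, 200, nrow(path))) {
    sel <- (pr - path$row[k])^2 + (pc - path$col[k])^2 <= r2
    expected <- if (any(sel)) min(ons[fin[sel]]) else NA_real_
    expect_equal(prof$onset_s[k], expected)
  }
})

test_that("Theil-Sen velocity estimation is exact on clean profiles and robust", {
  d <- seq(0, 2, by = 0.05)
  mk <- function(v) {
    p <- data.frame(distance_mm = d, onset_s = d * 1e-3 / v)
    class(p) <- c("axis_profile", class(p)); p
  }
  expect_equal(estimate_velocity(mk(0.37))$velocity_ms, 0.37, tolerance = 1e-9)
  expect_equal(estimate_velocity(mk(0.17))$velocity_ms, 0.17, tolerance = 1e-9)
  short <- mk(0.3)[1:3, ]
  expect_error(estimate_velocity(short), "at least 4")
  flat <- mk(0.3); flat$onset_s <- 0.5
  v <- estimate_velocity(flat)
  expect_true(v$infinite)
  expect_identical(v$velocity_ms, Inf)
  # one outlier in 20 samples moves the velocity by < 10%
  p <- mk(0.37)[1:20, ]
  v0 <- estimate_velocity(p)$velocity_ms
  p$onset_s[10] <- p$onset_s[10] + 0.05
  v1 <- estimate_velocity(p)$velocity_ms
  expect_lt(abs(v1 - v0) / v0, 0.10)
  # OLS alternative is available
  expect_equal(estimate_velocity(mk(0.2), method = "ols")$velocity_ms, 0.2,
               tolerance = 1e-9)
})

test_that("conduction times are earliest-onset differences with guards", {
  ab <- binned_atlas()
  fx <- event_fixture("noisy3a")
  om <- fx$rec$onset_map
  expect_equal(conduction_time(om, ab, "CA1", "CA1"), 0)
  expect_equal(conduction_time(om, ab, "CA1", "Au1_L56"), 25, tolerance = 5)
  empty <- om
  empty$onset_s[region_mask(ab, "Au1_L23")] <- NA_real_
  expect_error(conduction_time(empty, ab, "CA1", "Au1_L23"), "Au1_L23")
})

test_that("saltation detection finds the generated jumps and backfill velocity", {
  # monotonic profile -> no saltations
  d <- seq(0, 3, by = 0.05)
  p <- data.frame(distance_mm = d, onset_s = d * 0.002)
  class(p) <- c("axis_profile", class(p))
  expect_identical(nrow(detect_saltation(p)), 0L)
  fx <- event_fixture("noisy3a")
  prof <- fx$rec$axis_profiles$periallocortical
  # restricted to the periallocortical span: exactly the two generated jumps
  sub <- prof[prof$distance_mm <= 6.6, ]
  salt <- detect_saltation(sub)
  expect_identical(nrow(salt), 2L)
  expect_equal(salt$jump_to_mm, c(3.475, 6.475), tolerance = 0.2)
  expect_equal(salt$backfill_velocity_ms[1L], 0.47, tolerance = 0.11)
})

test_that("regional peak dF/F equals a brute-force maximum of the mean trace", {
  ab <- binned_atlas()
  fx <- event_fixture("noisy3a")
  dff <- fx$rec$dff
  # brute-force oracle
  mask <- region_mask(ab, "mEC")
  tr <- sapply(seq_len(dim(dff$frames)[1L]),
               function(t) mean(dff$frames[t, , ][mask]))
  expect_equal(peak_dff(dff, ab, "mEC"), max(tr), tolerance = 1e-12)
  # generated amplitude is recovered (0.16% at the CA1 origin)
  expect_equal(peak_dff(dff, ab, "CA1"), 0.16, tolerance = 0.03)
  # a never-active region has ~zero peak (noise only)
  zero <- flat_movie(0, t = 40, h = nrow(ab$label_image),
                     w = ncol(ab$label_image))
  expect_equal(peak_dff(zero, ab, "CA1"), 0)
})

test_that("onset-map cleanup removes isolated deviant pixels only", {
  h <- 30; w <- 30
  ons <- matrix(rep(seq(0.5, 0.53, length.out = w), each = h), h, w)
  dirty <- ons
  dirty[15, 15] <- dirty[15, 15] - 0.05    # isolated early artefact
  dirty[3, 3] <- NA
  cleaned <- clean_onset_map(dirty)
  expect_true(is.na(cleaned[15, 15]))
  keep <- !is.na(cleaned) & !is.na(dirty)
  expect_equal(cleaned[keep], dirty[keep])
  expect_gt(sum(is.finite(cleaned)), h * w - 5)
})
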