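test_that("background subtraction zeroes the baseline epoch", {
  expect_true(all(background_subtract(flat_movie(42, t = 120))$frames == 0))
  # a step after the baseline keeps its amplitude
  f <- array(0, c(120, 2, 2)); f[101:120, , ] <- 10
  out <- background_subtract(vsd_movie(f + 5, 200, 0.025), c(0, 0.5))
  expect_equal(max(out$frames) - min(out$frames), 10)
  # postcondition: per-pixel baseline means ~ 0
  set.seed(2)
  mv <- vsd_movie(array(rnorm(120 * 9, 100), c(120, 3, 3)), 200, 0.025)
  out <- background_subtract(mv, c(0, 0.5))
  base <- ictalwave:::frames_as_matrix(out$frames)[1:100, ]
  expect_lt(max(abs(colMeans(base))), 1e-9)
})

test_that("detrend removes a linear ramp and matches a per-pixel lm oracle", {
  mv <- ramp_movie(slope = 3, t = 150)
  out <- detrend(mv, c(0, 0.5))
  expect_lt(max(abs(out$frames)), 1e-6 * diff(range(mv$frames)))
  # oracle: explicit lm fit on the baseline, extrapolated
  set.seed(3)
  f <- array(rnorm(150 * 4, 50, 2), c(150, 2, 2))
  mv <- vsd_movie(f, 200, 0.025)
  out <- detrend(mv, c(0, 0.5))
  tt <- ictalwave:::movie_times(mv)
  for (px in list(c(1, 1), c(2, 2))) {
    y <- f[, px[1L], px[2L]]
    fit <- lm(y[1:100] ~ tt[1:100])
    expected <- y - (coef(fit)[1L] + coef(fit)[2L] * tt)
    expect_equal(out$frames[, px[1L], px[2L]], unname(expected),
                 tolerance = 1e-9)
  }
})

test_that("detrend suppresses exponential bleach far below its raw amplitude", {
  tt <- (0:1999) / 200                      # 10 s
  f <- array(rep(1000 * exp(-0.01 * tt), 4), c(2000, 2, 2))
  mv <- vsd_movie(f, 200, 0.025)
  out <- detrend(mv, c(0, 0.5))
  raw_amplitude <- diff(range(f))           # ~95 counts over 10 s
  expect_lt(max(abs(out$frames)), raw_amplitude / 10)
  # numeric oracle: baseline-fitted line subtracted from the exact exponential
  y <- 1000 * exp(-0.01 * tt)
  fit <- lm(y[1:100] ~ tt[1:100])
  oracle <- y - (coef(fit)[1L] + coef(fit)[2L] * tt)
  expect_equal(out$frames[, 1, 1], unname(oracle), tolerance = 1e-9)
})

test_that("spatial binning equals brute-force block means", {
  cb <- matrix(0, 4, 4); cb[cbind(rep(1:4, 2), c(1, 2, 3, 4, 3, 4, 1, 2))] <- 1
  cb <- (outer(1:4, 1:4, "+")) %% 2         # checkerboard
  mv <- vsd_movie(array(rep(cb, each = 3), c(3, 4, 4)), 200, 0.025)
  out <- spatial_bin(mv, 2L)
  expect_true(all(out$frames == 0.5))
  expect_equal(out$pixel_pitch, 0.05)
  expect_identical(spatial_bin(mv, 1L), mv)
  # brute-force oracle on a random 6x6 frame
  set.seed(4)
  f <- array(rnorm(2 * 36), c(2, 6, 6))
  out <- spatial_bin(vsd_movie(f, 200, 0.025), 2L)
  oracle <- array(0, c(2, 3, 3))
  for (t in 1:2) for (i in 1:3) for (j in 1:3)
    oracle[t, i, j] <- mean(f[t, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(out$frames, oracle, tolerance = 1e-12)
})

test_that("Savitzky-Golay differentiation reproduces analytic derivatives", {
  fs <- 200; tt <- (0:199) / fs
  # linear ramp: slope everywhere, interior exact
  d <- savgol_differentiate(3 * tt, window = 11L, order = 3L, fs = fs)
  expect_lt(max(abs(d - 3)), 1e-9)
  # constant: zero
  expect_lt(max(abs(savgol_differentiate(rep(7, 200), 11L, 3L, fs = fs))), 1e-9)
  # cubic polynomial (degree = order): interior exact
  y <- 2 * tt^3 - tt^2 + 5 * tt
  d <- savgol_differentiate(y, 11L, 3L, fs = fs)
  dy <- 6 * tt^2 - 2 * tt + 5
  expect_lt(max(abs(d - dy)[6:195]), 1e-6)
  # 2 Hz sinusoid at 200 Hz, window 11, order 3: within 1% of 2*pi*f*cos
  y <- sin(2 * pi * 2 * tt)
  d <- savgol_differentiate(y, 11L, 3L, fs = fs)
  expected <- 2 * pi * 2 * cos(2 * pi * 2 * tt)
  expect_lt(max(abs(d - expected)[6:195]) / (2 * pi * 2), 0.01)
  expect_error(savgol_differentiate(y, 10L, 3L, fs = fs), "odd")
  # movie and trace methods agree with the vector path
  mv <- ramp_movie(slope = 2, t = 60)
  dm <- savgol_differentiate(mv)
  expect_equal(max(abs(dm$frames - 2)), 0, tolerance = 1e-9)
})

test_that("percent dF/F conversion and its guards", {
  f <- array(1000, c(120, 2, 2)); f[110, , ] <- 1001.4
  out <- to_dff(vsd_movie(f, 200, 0.025), c(0, 0.5))
  expect_equal(max(out$frames), 0.14, tolerance = 1e-9)
  expect_true(all(to_dff(flat_movie(500, t = 120))$frames == 0))
  f0 <- array(0, c(120, 2, 2))
  expect_error(to_dff(vsd_movie(f0, 200, 0.025)), "baseline")
})

test_that("the conditioning chain is shape-stable and deterministic", {
  set.seed(5)
  mv <- vsd_movie(array(rnorm(150 * 8 * 8, 1000, 2), c(150, 8, 8)), 200, 0.025)
  a <- preprocess_movie(mv)
  b <- preprocess_movie(mv)
  expect_identical(a$deriv$frames, b$deriv$frames)
  expect_identical(dim(a$dff$frames), c(150L, 4L, 4L))
  expect_identical(dim(a$deriv$frames), dim(a$dff$frames))
})
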