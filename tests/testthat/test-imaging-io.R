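test_that("movie TIFF round trip is lossless on integer data and metadata", {
  td <- withr::local_tempdir()
  set.seed(1)
  mv <- vsd_movie(array(sample(0:65535, 10 * 4 * 4, TRUE), c(10, 4, 4)),
                  frame_rate = 200, pixel_pitch = 0.025)
  path <- file.path(td, "movie.tif")
  write_movie(mv, path)
  back <- read_movie(path)
  expect_equal(back$frames, mv$frames, tolerance = 0, ignore_attr = FALSE)
  expect_identical(dim(back$frames)[1L], 10L)   # one frame per TIFF page
  expect_equal(back$frame_rate, 200)
  expect_equal(back$pixel_pitch, 0.025)
})

test_that("movie reading rejects malformed inputs", {
  td <- withr::local_tempdir()
  # RGB TIFF is not a grayscale stack
  rgb <- file.path(td, "rgb.tif")
  tiff::writeTIFF(array(runif(4 * 4 * 3), c(4, 4, 3)), rgb)
  jsonlite::write_json(list(frame_rate = 200, pixel_pitch = 0.025),
                       paste0(rgb, ".json"), auto_unbox = TRUE)
  expect_error(read_movie(rgb), "grayscale")
  # missing sidecar names the expected path
  lone <- file.path(td, "lone.tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), lone)
  expect_error(read_movie(lone), "lone.tif.json", fixed = TRUE)
  expect_error(write_movie(flat_movie(70000), file.path(td, "x.tif")),
               "16-bit")
})

test_that("atlas round trip preserves labels, names and axis paths", {
  td <- withr::local_tempdir()
  atlas <- default_atlas()
  path <- file.path(td, "atlas.tif")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_identical(back$label_image, atlas$label_image)
  expect_equal(unname(back$label_names), unname(atlas$label_names))
  expect_equal(back$axis_paths, atlas$axis_paths, tolerance = 1e-9)
  expect_equal(back$pixel_pitch, atlas$pixel_pitch)
  # labels missing from the names map are rejected
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$label_names[["8"]] <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_atlas(path), "absent from the names map")
})

test_that("onset maps round trip through CSV with NA preserved", {
  td <- withr::local_tempdir()
  om <- ictalwave:::new_onset_map(
    matrix(c(0.1, NA, 0.25, 1.5, NA, 0.75), 2, 3),
    matrix(2, 2, 3), 200, 0.05)
  path <- file.path(td, "onsets.csv")
  write_onset_map(om, path)
  back <- read_onset_map(path)
  expect_equal(back$onset_s, om$onset_s)
  expect_equal(back$threshold_map, om$threshold_map)
  expect_equal(back$frame_rate, 200)
})

test_that("point-cloud export writes one row per finite onset with mm coords", {
  td <- withr::local_tempdir()
  ons <- matrix(NA_real_, 4, 5)
  ons[cbind(c(1, 2, 3, 3, 4), c(1, 2, 4, 3, 5))] <- c(0.5, 0.1, 0.2, 0.3, 0.4)
  path <- file.path(td, "pc.csv")
  export_pointcloud(ons, path, pixel_pitch = 0.025)
  df <- utils::read.csv(path)
  expect_identical(nrow(df), 5L)
  # pixel (row 2, col 3) 0-based at 25 um pitch -> x 0.075, y 0.050
  row23 <- df[df$t_s == 0.2, ]
  expect_equal(row23$x_mm, 0.075)
  expect_equal(row23$y_mm, 0.050)
  # all-NA map -> header-only file
  empty <- file.path(td, "empty.csv")
  export_pointcloud(matrix(NA_real_, 3, 3), empty, pixel_pitch = 0.025)
  expect_identical(nrow(utils::read.csv(empty)), 0L)
})

test_that("LFP traces round trip through two-column CSV", {
  td <- withr::local_tempdir()
  tr <- lfp_trace(sin(seq(0, 10, length.out = 400)) * 20, 2000, "L2/3")
  path <- file.path(td, "lfp.csv")
  write_lfp(tr, path)
  back <- read_lfp(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-9)
  expect_identical(back$channel, "L2/3")
  expect_equal(back$sample_rate, 2000)
})
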