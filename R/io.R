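#' On-disk formats
#'
#' Movies and atlas label images are stored as multi-page 16-bit grayscale
#' TIFF stacks with a JSON sidecar (`<file>.json`) carrying sampling
#' metadata.  Onset maps are stored as plain-text CSV matrices (NA = never
#' active) with a JSON sidecar, traces and tables as headed CSV.  All
#' read/write pairs are lossless round trips on valid inputs (integer data
#' bit-exact, floats at full precision).
#'
#' @name imaging_io
NULL

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing JSON sidecar: expected '%s'", sc))
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write / read a VSD movie as a multi-page 16-bit grayscale TIFF
#'
#' Values are camera counts in `[0, 65535]`, rounded to integers on write;
#' `frame_rate` and `pixel_pitch` travel in the JSON sidecar.
#'
#' @param movie a `vsd_movie`.
#' @param path TIFF file path (sidecar written next to it).
#' @return `write_movie`: the path, invisibly.  `read_movie`: a `vsd_movie`.
#' @export
write_movie <- function(movie, path) {
  f <- movie$frames
  if (min(f) < 0 || max(f) > 65535)
    stop("movie values outside the 16-bit range [0, 65535]")
  pages <- lapply(seq_len(dim(f)[1L]), function(t) round(f[t, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(kind = "vsd_movie", frame_rate = movie$frame_rate,
         pixel_pitch = movie$pixel_pitch, n_frames = dim(f)[1L],
         height = dim(f)[2L], width = dim(f)[3L]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("not a grayscale TIFF stack (multi-channel pages found)")
  arr <- array(0, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  vsd_movie(arr, meta$frame_rate, meta$pixel_pitch)
}

#' Write / read a region atlas
#'
#' The label image goes to a single-page 16-bit TIFF, names and axis paths
#' to the JSON sidecar.
#'
#' @param atlas a `region_atlas`.
#' @param path TIFF file path for the label image.
#' @return `write_atlas`: the path, invisibly.  `read_atlas`: a
#'   `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  tiff::writeTIFF(atlas$label_image / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(kind = "region_atlas",
         pixel_pitch = atlas$pixel_pitch,
         label_names = as.list(atlas$label_names),
         axis_paths = lapply(atlas$axis_paths, as.list)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  meta <- read_sidecar(path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2L) stop("atlas label image must be grayscale")
  storage.mode(img) <- "integer"
  label_names <- unlist(meta$label_names)
  present <- setdiff(unique(as.vector(img)), 0L)
  unknown <- setdiff(as.character(present), names(label_names))
  if (length(unknown))
    stop("label image contains labels absent from the names map: ",
         paste(unknown, collapse = ", "))
  axes <- lapply(meta$axis_paths, function(p)
    data.frame(row = p$row, col = p$col, distance_mm = p$distance_mm))
  new_region_atlas(img, label_names, axes, meta$pixel_pitch)
}

#' Write / read an onset map
#'
#' Onset seconds as a CSV matrix (NA = never active); the threshold map and
#' sampling metadata travel alongside (`<path>.threshold.csv`,
#' `<path>.json`).
#'
#' @param onset_map an `onset_map`.
#' @param path CSV file path.
#' @return `write_onset_map`: the path, invisibly.  `read_onset_map`: an
#'   `onset_map`.
#' @export
write_onset_map <- function(onset_map, path) {
  utils::write.table(onset_map$onset_s, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(onset_map$threshold_map, paste0(path, ".threshold.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(kind = "onset_map", frame_rate = onset_map$frame_rate,
         pixel_pitch = onset_map$pixel_pitch),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_onset_map
#' @export
read_onset_map <- function(path) {
  meta <- read_sidecar(path)
  ons <- as.matrix(utils::read.table(path, sep = ","))
  thr <- as.matrix(utils::read.table(paste0(path, ".threshold.csv"), sep = ","))
  dimnames(ons) <- NULL; dimnames(thr) <- NULL
  new_onset_map(ons, thr, meta$frame_rate, meta$pixel_pitch)
}

#' Export an onset map as an (x, y, t) point cloud
#'
#' One CSV row per pixel with a finite onset: `x_mm = col * pitch`,
#' `y_mm = row * pitch` (0-based indices), `t_s` the onset time.  An all-NA
#' map yields a header-only file.
#'
#' @param onset_map an `onset_map` (or a plain matrix, then `pixel_pitch`
#'   must be given).
#' @param path CSV file path.
#' @param pixel_pitch mm/pixel override for plain matrices.
#' @return the path, invisibly.
#' @export
export_pointcloud <- function(onset_map, path, pixel_pitch = NULL) {
  if (inherits(onset_map, "onset_map")) {
    ons <- onset_map$onset_s
    pitch <- onset_map$pixel_pitch
  } else {
    ons <- onset_map
    pitch <- pixel_pitch %||% stop("pixel_pitch required for plain matrices")
  }
  fin <- which(is.finite(ons))
  h <- nrow(ons)
  df <- data.frame(
    x_mm = ((fin - 1L) %/% h) * pitch,
    y_mm = ((fin - 1L) %% h) * pitch,
    t_s = ons[fin])
  df <- df[order(df$t_s, df$x_mm, df$y_mm), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an LFP trace as two-column CSV
#'
#' Columns `time_s`, `value_uV`; metadata (`sample_rate`, `channel`) in the
#' JSON sidecar.
#'
#' @param trace an `lfp_trace`.
#' @param path CSV file path.
#' @return `write_lfp`: the path, invisibly.  `read_lfp`: an `lfp_trace`.
#' @export
write_lfp <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace_times(trace),
                              value_uV = trace$samples),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(kind = "lfp_trace", sample_rate = trace$sample_rate,
         channel = trace$channel),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  meta <- read_sidecar(path)
  df <- utils::read.csv(path)
  lfp_trace(df$value_uV, meta$sample_rate, meta$channel)
}

#' Flatten event records into the event table
#'
#' One row per event with the documented column schema (type, origin,
#' laminar origin, spreads, conduction times, reverberation, CA1 velocity,
#' saltation count).
#'
#' @param records list of `event_record`s.
#' @param ids optional event ids.
#' @return data.frame.
#' @export
event_records_table <- function(records, ids = seq_along(records)) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(
      event_id = ids[i],
      event_type = r$event_type,
      origin_region = r$origin_region %||% NA_character_,
      origin_row = unname(r$origin_xy[1L]),
      origin_col = unname(r$origin_xy[2L]),
      origin_time_s = r$origin_time_s,
      recruited_regions = paste(r$recruited_regions, collapse = ";"),
      laminar_origin = r$laminar_origin,
      spread_l23_mm = unname(r$spread_mm["Au1_L23"]),
      spread_l56_mm = unname(r$spread_mm["Au1_L56"]),
      ct_ca1_au1_ms = r$conduction_times_ms[["CA1->Au1_L56"]] %||% NA_real_,
      ct_l23_l56_ms = r$conduction_times_ms[["Au1_L23->Au1_L56"]] %||% NA_real_,
      reverberates = r$reverberates,
      reverb_latency_s = r$reverb_latency_s,
      velocity_ca1_ms = r$velocity_ca1_ms,
      peak_dff_origin = r$peak_dff_origin,
      n_saltations = nrow(r$saltations),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
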