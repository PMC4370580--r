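#' Region atlases for slice imaging
#'
#' A `region_atlas` delineates the anatomical regions of a
#' hippocampal-neocortical slice on the camera pixel grid and carries the
#' 1-D anatomical axis paths along which wavefront propagation is measured.
#'
#' Coordinate conventions (fixed for all conduction-time math): pixels are
#' 0-based `(row, col)` with row 0 at the top; physical `x = col * pitch`,
#' `y = row * pitch` in mm; times are seconds from frame 0.
#'
#' @name region_atlas
NULL

new_region_atlas <- function(label_image, label_names, axis_paths, pixel_pitch) {
  structure(
    list(label_image = label_image,
         label_names = label_names,
         axis_paths = axis_paths,
         pixel_pitch = pixel_pitch),
    class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas> %d x %d px @ %.3f mm/px\n",
              nrow(x$label_image), ncol(x$label_image), x$pixel_pitch))
  cat("  regions:", paste(x$label_names, collapse = ", "), "\n")
  for (nm in names(x$axis_paths)) {
    p <- x$axis_paths[[nm]]
    cat(sprintf("  axis %-24s %.2f mm, %d samples\n",
                nm, max(p$distance_mm), nrow(p)))
  }
  invisible(x)
}

# Vectorised even-odd (ray casting) point-in-polygon test.
# px, py: point coords; vx, vy: polygon vertices (closed implicitly).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Cumulative arc length (in mm) of a polyline given pixel-coordinate
# waypoints; returns per-step sample points at ~1 px spacing.
sample_polyline <- function(waypoints_rc, pixel_pitch) {
  wp <- as.matrix(waypoints_rc)            # columns: row, col (0-based)
  pts_r <- numeric(0); pts_c <- numeric(0)
  for (k in seq_len(nrow(wp) - 1L)) {
    a <- wp[k, ]; b <- wp[k + 1L, ]
    seg_px <- max(abs(b - a))
    n <- max(1L, ceiling(seg_px))
    f <- seq(0, 1, length.out = n + 1L)
    if (k > 1L) f <- f[-1L]                # avoid duplicating waypoints
    pts_r <- c(pts_r, a[1L] + f * (b[1L] - a[1L]))
    pts_c <- c(pts_c, a[2L] + f * (b[2L] - a[2L]))
  }
  d <- c(0, cumsum(sqrt(diff(pts_r)^2 + diff(pts_c)^2))) * pixel_pitch
  data.frame(row = pts_r, col = pts_c, distance_mm = d)
}

#' Build a region atlas from a geometry configuration
#'
#' Rasterises region polygons onto the pixel grid (every pixel gets at most
#' one label; overlap is an error) and converts axis waypoint lists into
#' polylines with cumulative distance in mm.
#'
#' @param config list with `height`, `width` (pixels), `pixel_pitch_mm`,
#'   `regions` (named list; each entry a list with `x` and `y` polygon vertex
#'   vectors in 0-based pixel coordinates) and `axes` (named list; each entry
#'   a matrix/data.frame of `(row, col)` waypoints).  `default_atlas_config()`
#'   supplies the bundled schematic slice geometry.
#' @return a `region_atlas`.
#' @export
build_region_atlas <- function(config = default_atlas_config()) {
  h <- config$height; w <- config$width
  pitch <- config$pixel_pitch_mm
  stop_if_not_scalar_number(pitch, "pixel_pitch_mm")
  lab <- matrix(0L, h, w)
  # pixel centres, 0-based
  rows <- rep(0:(h - 1L), times = w)
  cols <- rep(0:(w - 1L), each = h)
  label_names <- character(0)
  for (i in seq_along(config$regions)) {
    rg <- config$regions[[i]]
    nm <- names(config$regions)[i]
    inside <- points_in_polygon(cols, rows, rg$x, rg$y)
    if (any(lab[inside] != 0L))
      stop(sprintf("region polygons overlap (while adding '%s')", nm))
    lab[inside] <- i
    label_names[i] <- nm
  }
  names(label_names) <- as.character(seq_along(label_names))
  axes <- list()
  for (nm in names(config$axes)) {
    wp <- as.matrix(config$axes[[nm]])
    if (any(wp[, 1L] < 0) || any(wp[, 1L] > h - 1L) ||
        any(wp[, 2L] < 0) || any(wp[, 2L] > w - 1L))
      stop(sprintf("axis path '%s' leaves the pixel grid", nm))
    axes[[nm]] <- sample_polyline(wp, pitch)
    if (any(diff(axes[[nm]]$distance_mm) <= 0))
      stop(sprintf("axis path '%s' has non-increasing distance", nm))
  }
  new_region_atlas(lab, label_names, axes, pitch)
}

# Rectangle polygon helper (0-based pixel index ranges, inclusive).
# Vertices are placed half a pixel outside the index range so that pixel
# centres at the boundary are unambiguous.
rect_region <- function(col0, col1, row0, row1) {
  list(x = c(col0 - 0.5, col1 + 0.5, col1 + 0.5, col0 - 0.5),
       y = c(row0 - 0.5, row0 - 0.5, row1 + 0.5, row1 + 0.5))
}

#' Default schematic slice geometry
#'
#' A schematic horizontal-slice atlas on a 100 x 440 pixel grid at 25 um/px
#' (2.5 mm x 11 mm).  Regions are laid out along the hippocampo-neocortical
#' axis: CA3 (0-0.5 mm), CA1 (0.5-2.5 mm), subiculum (2.5-3 mm),
#' mEC (3-6 mm), lEC (6-9 mm), perirhinal cortex (9-9.5 mm), and primary
#' auditory cortex Au1 (9.5-11 mm) split into superficial (layers 2/3, upper
#' half) and deep (layers 5/6, lower half) laminae.  Axis paths: the cornu
#' ammonis axis (CA3 end to the subiculum), the periallocortical axis with
#' zero at the CA1/subiculum border, the full hippocampo-neocortical axis,
#' and a radial Au1 laminar axis from pia to white matter.
#'
#' @param pixel_pitch_mm mm per pixel (default 0.025).
#' @return geometry config list for [build_region_atlas()].
#' @export
default_atlas_config <- function(pixel_pitch_mm = 0.025) {
  list(
    height = 100L, width = 440L, pixel_pitch_mm = pixel_pitch_mm,
    regions = list(
      CA3        = rect_region(0L,   19L,  0L, 99L),
      CA1        = rect_region(20L,  99L,  0L, 99L),
      subiculum  = rect_region(100L, 119L, 0L, 99L),
      mEC        = rect_region(120L, 239L, 0L, 99L),
      lEC        = rect_region(240L, 359L, 0L, 99L),
      perirhinal = rect_region(360L, 379L, 0L, 99L),
      Au1_L23    = rect_region(380L, 439L, 0L, 49L),
      Au1_L56    = rect_region(380L, 439L, 50L, 99L)
    ),
    axes = list(
      cornu_ammonis           = rbind(c(50, 0), c(50, 119)),
      periallocortical        = rbind(c(75, 100), c(75, 439)),
      hippocampo_neocortical  = rbind(c(75, 0), c(75, 439)),
      au1_laminar             = rbind(c(0, 410), c(99, 410))
    )
  )
}

#' Region labels counted as hippocampal
#' @keywords internal
hippocampal_labels <- function() c("CA1", "CA3")

#' Pixel mask for a named region
#'
#' @param atlas a `region_atlas`.
#' @param region region name; `"Au1"` unions both Au1 laminae,
#'   `"hippocampus"` unions CA1 and CA3.
#' @return logical H x W matrix.
#' @export
region_mask <- function(atlas, region) {
  nm <- atlas$label_names
  ids <- switch(region,
    Au1 = which(nm %in% c("Au1_L23", "Au1_L56")),
    hippocampus = which(nm %in% hippocampal_labels()),
    which(nm == region))
  if (!length(ids)) stop(sprintf("region '%s' not present in atlas", region))
  matrix(atlas$label_image %in% ids,
         nrow(atlas$label_image), ncol(atlas$label_image))
}

#' Downsample an atlas to match a spatially binned movie
#'
#' Each `factor x factor` block takes the majority label of its pixels; axis
#' path coordinates are rescaled (physical positions unchanged).
#'
#' @param atlas a `region_atlas`.
#' @param factor integer bin factor (same as [spatial_bin()]).
#' @return a `region_atlas` on the binned grid.
#' @export
bin_atlas <- function(atlas, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(atlas)
  lab <- atlas$label_image
  h <- (nrow(lab) %/% factor) * factor
  w <- (ncol(lab) %/% factor) * factor
  lab <- lab[seq_len(h), seq_len(w), drop = FALSE]
  hb <- h %/% factor; wb <- w %/% factor
  # majority vote per block
  block_of <- function(m) {
    idx <- array(m, c(factor, hb, factor, wb))
    apply(idx, c(2L, 4L), function(v) {
      tb <- tabulate(v + 1L)
      which.max(tb) - 1L
    })
  }
  labb <- block_of(lab)
  axes <- lapply(atlas$axis_paths, function(p) {
    p$row <- (p$row + 0.5) / factor - 0.5
    p$col <- (p$col + 0.5) / factor - 0.5
    p
  })
  new_region_atlas(labb, atlas$label_names, axes, atlas$pixel_pitch * factor)
}
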