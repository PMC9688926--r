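#' Acquisition geometry of a tiled z-stack time-lapse recording
#'
#' Describes the layout of a multi-position brightfield recording: a grid of
#' camera tiles with a fixed fractional overlap, a z-stack per tile, and a
#' fixed recording interval. Defaults mirror a typical organoid culture
#' recording: 2 x 2 tiles at 15% overlap acquired in meander (serpentine)
#' order, 10 z-planes spaced 65 um, square 1.29 um pixels, and 97 frames at
#' 0.5 h intervals (48 h with 0 h counted as time point 1).
#'
#' @param tile_rows,tile_cols tile grid size.
#' @param overlap_fraction fraction of tile width/height shared by adjacent
#'   tiles; must lie in `[0, 0.5)`.
#' @param scan_mode `"meander"` (serpentine) or `"row_major"` acquisition
#'   order.
#' @param z_planes number of z-planes per tile.
#' @param z_spacing_um spacing between z-planes in micrometres.
#' @param pixel_size_um edge length of the square pixels in micrometres.
#' @param n_frames number of time points (>= 1).
#' @param interval_h time between frames in hours.
#' @param tile_shape_px integer `(height, width)` of one tile in pixels.
#' @return An object of class `acquisition_geometry`.
#' @examples
#' geom <- acquisition_geometry(tile_shape_px = c(128, 128), n_frames = 5)
#' mosaic_shape(geom)
#' @export
acquisition_geometry <- function(tile_rows = 2L, tile_cols = 2L,
                                 overlap_fraction = 0.15,
                                 scan_mode = c("meander", "row_major"),
                                 z_planes = 10L, z_spacing_um = 65,
                                 pixel_size_um = 1.29,
                                 n_frames = 97L, interval_h = 0.5,
                                 tile_shape_px = c(256L, 256L)) {
  scan_mode <- match.arg(scan_mode)
  stopifnot(
    tile_rows >= 1, tile_cols >= 1,
    overlap_fraction >= 0, overlap_fraction < 0.5,
    z_planes >= 1, z_spacing_um > 0,
    pixel_size_um > 0, n_frames >= 1, interval_h > 0,
    length(tile_shape_px) == 2, all(tile_shape_px >= 8)
  )
  structure(list(
    tile_rows = as.integer(tile_rows), tile_cols = as.integer(tile_cols),
    overlap_fraction = overlap_fraction, scan_mode = scan_mode,
    z_planes = as.integer(z_planes), z_spacing_um = z_spacing_um,
    pixel_size_um = pixel_size_um, n_frames = as.integer(n_frames),
    interval_h = interval_h, tile_shape_px = as.integer(tile_shape_px)
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "<acquisition_geometry> %dx%d tiles (%.0f%% overlap, %s), %d z-planes @ %g um,\n  %d frames @ %g h, tile %dx%d px, pixel %g um\n",
    x$tile_rows, x$tile_cols, 100 * x$overlap_fraction, x$scan_mode,
    x$z_planes, x$z_spacing_um, x$n_frames, x$interval_h,
    x$tile_shape_px[1], x$tile_shape_px[2], x$pixel_size_um
  ))
  invisible(x)
}

#' Number of time points in a recording
#'
#' A recording of `duration_h` hours at a fixed interval, counting 0 h as the
#' first time point, comprises `duration_h / interval_h + 1` frames (e.g.
#' 48 h at 0.5 h intervals gives 97).
#'
#' @param duration_h total recording duration in hours (>= 0).
#' @param interval_h interval between frames in hours; must divide the
#'   duration.
#' @return Integer frame count.
#' @examples
#' frame_count(48, 0.5) # 97
#' @export
frame_count <- function(duration_h, interval_h) {
  stopifnot(duration_h >= 0, interval_h > 0)
  k <- duration_h / interval_h
  if (abs(k - round(k)) > 1e-9)
    stop("interval_h (", interval_h, ") does not divide duration_h (",
         duration_h, ")")
  as.integer(round(k)) + 1L
}

#' Tile acquisition order for a serpentine (meander) or row-major scan
#'
#' @param rows,cols tile grid size (>= 1).
#' @param scan_mode `"meander"` alternates direction row by row; `"row_major"`
#'   always scans left to right.
#' @return A `rows * cols` x 2 integer matrix of 0-based `(row, col)` grid
#'   positions in acquisition order.
#' @examples
#' meander_order(2, 2) # (0,0) (0,1) (1,1) (1,0)
#' @export
meander_order <- function(rows, cols, scan_mode = c("meander", "row_major")) {
  scan_mode <- match.arg(scan_mode)
  stopifnot(rows >= 1, cols >= 1)
  out <- matrix(0L, nrow = rows * cols, ncol = 2,
                dimnames = list(NULL, c("row", "col")))
  k <- 1L
  for (r in seq_len(rows) - 1L) {
    cs <- seq_len(cols) - 1L
    if (scan_mode == "meander" && r %% 2L == 1L) cs <- rev(cs)
    for (cc in cs) {
      out[k, ] <- c(r, cc)
      k <- k + 1L
    }
  }
  out
}

#' Nominal tile origins within the mosaic
#'
#' Top-left pixel of each tile in mosaic coordinates, from the nominal grid
#' spacing `tile_extent * (1 - overlap_fraction)` rounded to integer pixels.
#'
#' @param geometry an [acquisition_geometry()].
#' @return Data frame with columns `row`, `col`, `y0`, `x0` (0-based pixels),
#'   one row per tile in row-major grid order.
#' @export
tile_origins <- function(geometry) {
  th <- geometry$tile_shape_px[1]
  tw <- geometry$tile_shape_px[2]
  ov <- geometry$overlap_fraction
  grid <- expand.grid(col = seq_len(geometry$tile_cols) - 1L,
                      row = seq_len(geometry$tile_rows) - 1L)
  data.frame(
    row = grid$row, col = grid$col,
    y0 = as.integer(round(grid$row * (1 - ov) * th)),
    x0 = as.integer(round(grid$col * (1 - ov) * tw))
  )
}

#' Pixel dimensions of the stitched mosaic
#'
#' @param geometry an [acquisition_geometry()].
#' @return Integer `(height, width)` in pixels.
#' @export
mosaic_shape <- function(geometry) {
  org <- tile_origins(geometry)
  c(max(org$y0) + geometry$tile_shape_px[1],
    max(org$x0) + geometry$tile_shape_px[2])
}

# hours since recording start for each frame (0 h is frame 1)
frame_times_h <- function(geometry) {
  (seq_len(geometry$n_frames) - 1) * geometry$interval_h
}
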