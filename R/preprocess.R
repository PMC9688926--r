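#' Z-projection of a focal stack
#'
#' Collapses a `height x width x z` stack to one 2D image by average (the
#' default readout for brightfield organoid recordings) or maximum intensity.
#'
#' @param stack numeric array `height x width x z` (a plain matrix is treated
#'   as a single plane).
#' @param method `"average"` or `"max"`.
#' @return A numeric matrix.
#' @export
z_project <- function(stack, method = c("average", "max")) {
  method <- match.arg(method)
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3, dim(stack)[3] >= 1)
  if (method == "average") {
    rowMeans(stack, dims = 2)
  } else {
    out <- stack[, , 1]
    for (k in seq_len(dim(stack)[3])[-1]) out <- pmax(out, stack[, , k])
    out
  }
}

#' Stitch projected tiles into one mosaic frame
#'
#' Places the tiles of one time point on the nominal grid derived from the
#' acquisition geometry (spacing `tile_extent * (1 - overlap)`), optionally
#' refining each tile's offset by integer-pixel normalized cross-correlation
#' against its already-placed neighbour, bounded by half the overlap.
#' Overlapping pixels are blended by linear feathering (weights ramp linearly
#' with the distance to each tile's border), which reproduces the underlying
#' scene exactly wherever the tiles agree.
#'
#' @param tiles list of projected tile matrices in row-major grid order
#'   (row 0 first), as produced by the simulator or [z_project()].
#' @param geometry an [acquisition_geometry()].
#' @param refine estimate offsets by cross-correlation (`TRUE`) or use the
#'   nominal grid (`FALSE`). Degenerate overlaps (zero variance) fall back to
#'   the nominal offset with a warning.
#' @param frame frame number recorded in the result.
#' @param offsets optional precomputed offsets data frame (from a previous
#'   `stitch()` call) to reuse, skipping estimation.
#' @return An object of class `mosaic_frame`: list with `frame`, `image`
#'   (matrix) and `offsets` (data frame `row`, `col`, `y0`, `x0`).
#' @export
stitch <- function(tiles, geometry, refine = TRUE, frame = 1L,
                   offsets = NULL) {
  nt <- geometry$tile_rows * geometry$tile_cols
  if (length(tiles) != nt)
    stop("expected ", nt, " tiles, got ", length(tiles))
  th <- geometry$tile_shape_px[1]; tw <- geometry$tile_shape_px[2]
  for (t in tiles) stopifnot(nrow(t) == th, ncol(t) == tw)
  nominal <- tile_origins(geometry)

  if (is.null(offsets)) {
    offsets <- nominal
    if (refine && nt > 1) {
      bound_y <- floor(geometry$overlap_fraction * th / 2)
      bound_x <- floor(geometry$overlap_fraction * tw / 2)
      for (k in seq_len(nt)[-1]) {
        r <- nominal$row[k]; cc <- nominal$col[k]
        # anchor on the left neighbour if any, else the tile above
        if (cc > 0) {
          a <- which(nominal$row == r & nominal$col == cc - 1)
        } else {
          a <- which(nominal$row == r - 1 & nominal$col == cc)
        }
        rel_nom <- c(nominal$y0[k] - nominal$y0[a],
                     nominal$x0[k] - nominal$x0[a])
        sh <- estimate_shift(tiles[[a]], tiles[[k]], rel_nom,
                             bound_y, bound_x)
        if (is.null(sh)) {
          warning("degenerate or featureless overlap for tile (", r, ",",
                  cc, "); falling back to nominal offset")
          sh <- c(0L, 0L)
        }
        offsets$y0[k] <- offsets$y0[a] + rel_nom[1] + sh[1]
        offsets$x0[k] <- offsets$x0[a] + rel_nom[2] + sh[2]
      }
    }
  }

  H <- max(offsets$y0) + th; W <- max(offsets$x0) + tw
  acc <- matrix(0, H, W); wsum <- matrix(0, H, W)
  # linear feather: weight = distance to the nearest tile border (>= 1)
  wy <- pmin(seq_len(th), rev(seq_len(th)))
  wx <- pmin(seq_len(tw), rev(seq_len(tw)))
  wt <- outer(wy, wx, pmin)
  for (k in seq_len(nt)) {
    ri <- offsets$y0[k] + seq_len(th); ci <- offsets$x0[k] + seq_len(tw)
    acc[ri, ci] <- acc[ri, ci] + wt * tiles[[k]]
    wsum[ri, ci] <- wsum[ri, ci] + wt
  }
  img <- acc / pmax(wsum, .Machine$double.eps)
  img[wsum == 0] <- 0
  structure(list(frame = as.integer(frame), image = img, offsets = offsets),
            class = "mosaic_frame")
}

# integer-shift NCC between the overlap strips of two tiles whose nominal
# relative displacement is rel_nom = (dy, dx); returns the best (dy, dx)
# perturbation within the bound, or NULL when correlation is degenerate or
# too weak to trust (featureless overlap: noise-dominated peak)
estimate_shift <- function(ref, mov, rel_nom, bound_y, bound_x,
                           min_ncc = 0.3) {
  th <- nrow(ref); tw <- ncol(ref)
  best <- NULL; best_ncc <- -Inf
  for (dy in -bound_y:bound_y) for (dx in -bound_x:bound_x) {
    oy <- rel_nom[1] + dy; ox <- rel_nom[2] + dx
    # overlap of ref [1..th, 1..tw] with mov placed at (oy, ox)
    r1 <- max(1, 1 + oy); r2 <- min(th, th + oy)
    c1 <- max(1, 1 + ox); c2 <- min(tw, tw + ox)
    if (r2 - r1 < 4 || c2 - c1 < 4) next
    a <- ref[r1:r2, c1:c2]
    b <- mov[(r1:r2) - oy, (c1:c2) - ox]
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) next
    ncc <- mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
    better <- ncc > best_ncc + 1e-12 ||
      (abs(ncc - best_ncc) <= 1e-12 && !is.null(best) &&
       dy^2 + dx^2 < sum(best^2))
    if (better) { best_ncc <- ncc; best <- c(dy, dx) }
  }
  if (!is.null(best) && best_ncc < min_ncc) best <- NULL
  best
}

#' Project and stitch a whole recording
#'
#' Reduces one simulated/loaded recording (list of `h x w x z x frame` tile
#' arrays) to one stitched average-intensity projection per time point. By
#' default the stitching offsets are estimated once on the first frame and
#' reused for all frames (the stage does not move between time points);
#' per-frame estimation is available.
#'
#' @param recording list with `tiles` and `geometry` (one element of
#'   [simulate_recording()]'s `recordings`, or [read_image_stack()] output).
#' @param method projection method passed to [z_project()].
#' @param refine,per_frame_offsets offset refinement flags; see [stitch()].
#' @return List of `mosaic_frame` objects, one per frame.
#' @export
project_and_stitch <- function(recording, method = "average",
                               refine = TRUE, per_frame_offsets = FALSE) {
  geom <- recording$geometry
  nf <- geom$n_frames
  out <- vector("list", nf)
  offs <- NULL
  for (f in seq_len(nf)) {
    proj <- lapply(recording$tiles, function(a) z_project(a[, , , f,
                                                            drop = TRUE],
                                                          method))
    m <- stitch(proj, geom, refine = refine, frame = f, offsets = offs)
    if (!per_frame_offsets && is.null(offs)) offs <- m$offsets
    out[[f]] <- m
  }
  out
}
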