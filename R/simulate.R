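#' Configuration for the synthetic organoid recording generator
#'
#' Bundles an [acquisition_geometry()] with the biological and optical
#' parameters of the simulated culture. One tiled recording (one well) is
#' generated per condition; each condition is a named growth-inhibition
#' fraction `eta` in `[0, 1]`, and every organoid's projected luminal area
#' follows `A(t) = A(0) * exp(g * (1 - eta) * t)` with base area growth rate
#' `g` per hour. Organoids are rendered as a bright lumen disk bounded by a
#' darker epithelial ring (the brightfield appearance of a cystic organoid,
#' with configurable contrast polarity), with Gaussian defocus blur growing
#' with the z-distance from a per-organoid focal plane, a smooth
#' multiplicative illumination gradient, and additive Gaussian noise.
#'
#' The default organoid count (60) sits inside the 41-139 organoids per
#' Matrigel droplet observed in real cultures; the default growth rate
#' doubles-and-a-bit the untreated luminal area over 48 h (final/initial
#' ratio 2.3). Intensity levels and noise are not calibrated to any
#' physical camera; they are chosen so the downstream morphological
#' segmentation operates in a realistic contrast regime.
#'
#' @param geometry an [acquisition_geometry()].
#' @param n_organoids organoids per condition (per simulated well).
#' @param conditions named numeric vector of growth-inhibition fractions
#'   `eta`, e.g. `c(untreated = 0, sorafenib = 0.5)`.
#' @param base_growth_rate_per_h area growth rate `g` (1/h) of an untreated
#'   organoid.
#' @param initial_radius_um `(meanlog-scale mean, sdlog)` of the lognormal
#'   initial lumen radius: radii are `rlnorm(meanlog = log(mean), sdlog)`.
#' @param epithelial_ring_thickness_um thickness of the dark rim.
#' @param growth_rate_cv lognormal coefficient of variation of per-organoid
#'   growth rates (0 = all organoids grow at exactly `g * (1 - eta)`).
#' @param noise_sd additive Gaussian noise sd on the `[0, 1]` intensity
#'   scale, applied independently per tile/z-plane/frame.
#' @param illumination_gradient_amplitude peak-to-centre relative amplitude
#'   of a planar illumination gradient across the mosaic.
#' @param dropout_prob_per_frame probability that an organoid is invisible
#'   (not rendered) in any given frame, independently per frame.
#' @param levels intensity levels `c(background, lumen, ring)` in `[0, 1]`;
#'   swap lumen/background to invert contrast polarity.
#' @param base_blur_px in-focus Gaussian blur sigma (pixels).
#' @param defocus_px_per_um additional blur sigma per micrometre of
#'   z-distance from the organoid's focal plane.
#' @param separation_um minimum gap enforced between the *final* epithelial
#'   rims of any two organoids at placement time.
#' @param max_place_tries rejection-sampling attempts per organoid before
#'   the packing is declared infeasible.
#' @param seed integer seed fixing all stochastic draws end-to-end.
#' @return An object of class `simulation_config`.
#' @seealso [simulate_recording()], [demo_config()]
#' @export
simulation_config <- function(geometry = acquisition_geometry(),
                              n_organoids = 60L,
                              conditions = c(untreated = 0),
                              base_growth_rate_per_h = log(2.3) / 48,
                              initial_radius_um = c(16, 0.2),
                              epithelial_ring_thickness_um = 8,
                              growth_rate_cv = 0,
                              noise_sd = 0.015,
                              illumination_gradient_amplitude = 0.1,
                              dropout_prob_per_frame = 0,
                              levels = c(background = 0.5, lumen = 0.8,
                                         ring = 0.25),
                              base_blur_px = 0.8,
                              defocus_px_per_um = 0.03,
                              separation_um = 8,
                              max_place_tries = 5000L,
                              seed = 1L) {
  stopifnot(
    inherits(geometry, "acquisition_geometry"),
    n_organoids >= 1,
    length(conditions) >= 1, !is.null(names(conditions)),
    all(nzchar(names(conditions))),
    all(conditions >= 0 & conditions <= 1),
    base_growth_rate_per_h >= 0,
    length(initial_radius_um) == 2, initial_radius_um[1] > 0,
    initial_radius_um[2] >= 0,
    epithelial_ring_thickness_um > 0, growth_rate_cv >= 0,
    noise_sd >= 0, illumination_gradient_amplitude >= 0,
    dropout_prob_per_frame >= 0, dropout_prob_per_frame < 1,
    length(levels) == 3, all(levels >= 0 & levels <= 1),
    base_blur_px >= 0, defocus_px_per_um >= 0, separation_um >= 0
  )
  structure(list(
    geometry = geometry, n_organoids = as.integer(n_organoids),
    conditions = conditions,
    base_growth_rate_per_h = base_growth_rate_per_h,
    initial_radius_um = unname(initial_radius_um),
    epithelial_ring_thickness_um = epithelial_ring_thickness_um,
    growth_rate_cv = growth_rate_cv,
    noise_sd = noise_sd,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    dropout_prob_per_frame = dropout_prob_per_frame,
    levels = unname(levels), base_blur_px = base_blur_px,
    defocus_px_per_um = defocus_px_per_um,
    separation_um = separation_um,
    max_place_tries = as.integer(max_place_tries),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Compact two-condition demonstration pipeline configuration
#'
#' A scaled-down recording (2 x 2 tiles of 256 x 256 px, 3 z-planes, the full
#' 97 frames at 0.5 h) of ~40 organoids per well under two conditions: an
#' untreated well (final/initial luminal-area ratio 2.3 over 48 h) and a
#' treated well whose inhibition is set so the true final-size ratio between
#' the conditions is 0.49, the strongest effect reported for a
#' sub-therapeutic kinase-inhibitor dose in tumour organoids. The initial
#' radius dispersion is kept tight and the segmentation area cut-off lowered
#' to 250 um^2 so every simulated organoid stays safely detectable at its
#' smallest size. Used in examples and the package's end-to-end recovery
#' checks.
#'
#' @param seed integer seed.
#' @param n_organoids organoids per condition.
#' @param dropout_prob_per_frame per-frame invisibility probability.
#' @return A [pipeline_config()] (its `$simulation` is the generator
#'   configuration).
#' @export
demo_config <- function(seed = 1L, n_organoids = 40L,
                        dropout_prob_per_frame = 0) {
  eta <- 1 - (1 + log(0.49) / log(2.3)) # true final-size ratio 0.49
  sim <- simulation_config(
    geometry = acquisition_geometry(z_planes = 3L,
                                    tile_shape_px = c(256L, 256L)),
    n_organoids = n_organoids,
    conditions = c(untreated = 0, treated = eta),
    initial_radius_um = c(15, 0.1),
    dropout_prob_per_frame = dropout_prob_per_frame,
    seed = seed
  )
  pipeline_config(
    simulation = sim,
    segmentation = segmentation_params(min_area_um2 = 250),
    reference = "untreated"
  )
}

# evaluate code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate tiled brightfield-like recordings with ground truth
#'
#' Generates, for every condition in the configuration, one tiled z-stack
#' time-lapse recording of a simulated organoid culture, together with a
#' per-organoid, per-frame ground-truth table. Organoid centres are placed by
#' rejection sampling so that even the fully grown epithelial rims stay
#' separated; an infeasible packing raises an error naming the density limit.
#' Identical configurations (same seed) yield bit-identical images and
#' ground truth.
#'
#' @param config a [simulation_config()].
#' @return An object of class `organoid_simulation`: a list with
#'   \describe{
#'   \item{recordings}{named list (one per condition); each element has
#'     `tiles` (list of `height x width x z x frame` arrays on the `[0, 1]`
#'     intensity scale, in row-major grid order), `condition` and `geometry`.}
#'   \item{ground_truth}{data frame with columns `organoid_id`, `condition`,
#'     `frame`, `cx_um`, `cy_um`, `lumen_radius_um`, `true_lumen_area_um2`,
#'     `visible`.}
#'   \item{config}{the configuration used.}
#'   }
#' @examples
#' cfg <- simulation_config(
#'   geometry = acquisition_geometry(tile_rows = 1, tile_cols = 1,
#'     z_planes = 2, n_frames = 3, tile_shape_px = c(96, 96)),
#'   n_organoids = 2, seed = 7)
#' sim <- simulate_recording(cfg)
#' dim(sim$recordings$untreated$tiles[[1]])
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  recordings <- list()
  gt <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- names(config$conditions)[ci]
    sub_seed <- (config$seed + 7919L * (ci - 1L)) %% .Machine$integer.max
    res <- with_seed(sub_seed, simulate_condition(config, ci))
    recordings[[cond]] <- res$recording
    gt[[cond]] <- res$ground_truth
  }
  structure(list(
    recordings = recordings,
    ground_truth = do.call(rbind, c(gt, list(make.row.names = FALSE))),
    config = config
  ), class = "organoid_simulation")
}

# one condition = one well = one tiled recording
simulate_condition <- function(config, ci) {
  geom <- config$geometry
  eta <- unname(config$conditions[ci])
  cond <- names(config$conditions)[ci]
  px <- geom$pixel_size_um
  msh <- mosaic_shape(geom)
  H_um <- (msh[1] - 1) * px
  W_um <- (msh[2] - 1) * px
  tt <- frame_times_h(geom)
  n <- config$n_organoids

  # per-organoid kinetics: lumen radius r(t) = r0 * exp(g_area/2 * t)
  r0 <- rlnorm(n, meanlog = log(config$initial_radius_um[1]),
               sdlog = config$initial_radius_um[2])
  g_mult <- if (config$growth_rate_cv > 0)
    rlnorm(n, meanlog = -config$growth_rate_cv^2 / 2,
           sdlog = config$growth_rate_cv) else rep(1, n)
  g_area <- config$base_growth_rate_per_h * (1 - eta) * g_mult
  r_final <- r0 * exp(g_area / 2 * max(tt))
  ring <- config$epithelial_ring_thickness_um

  # rejection-sampled placement: final rims must not touch
  ctr <- place_organoids(n, r_final + ring, H_um, W_um,
                         config$separation_um, config$max_place_tries)

  focal_plane <- if (geom$z_planes > 1)
    sample.int(geom$z_planes, n, replace = TRUE) else rep(1L, n)
  visible <- matrix(TRUE, n, geom$n_frames)
  if (config$dropout_prob_per_frame > 0)
    visible <- matrix(rbinom(n * geom$n_frames, 1L,
                             1 - config$dropout_prob_per_frame) == 1L,
                      n, geom$n_frames)

  illum_theta <- runif(1, 0, 2 * pi)
  radius_t <- outer(r0, rep(1, geom$n_frames)) *
    exp(outer(g_area / 2, tt))

  rec <- render_condition(config, ctr, radius_t, ring, focal_plane,
                          visible, illum_theta)
  rec$condition <- cond
  rec$geometry <- geom

  gt <- data.frame(
    organoid_id = rep(seq_len(n), each = geom$n_frames),
    condition = cond,
    frame = rep(seq_len(geom$n_frames), times = n),
    cx_um = rep(ctr[, 1], each = geom$n_frames),
    cy_um = rep(ctr[, 2], each = geom$n_frames),
    lumen_radius_um = as.vector(t(radius_t)),
    visible = as.vector(t(visible))
  )
  gt$true_lumen_area_um2 <- pi * gt$lumen_radius_um^2
  gt <- gt[, c("organoid_id", "condition", "frame", "cx_um", "cy_um",
               "lumen_radius_um", "true_lumen_area_um2", "visible")]
  list(recording = rec, ground_truth = gt)
}

place_organoids <- function(n, r_excl, H_um, W_um, separation_um,
                            max_tries) {
  edge <- r_excl + separation_um
  if (any(2 * edge >= W_um | 2 * edge >= H_um))
    stop("organoid exclusion radius exceeds the field; reduce radii or ",
         "enlarge the mosaic")
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      x <- runif(1, edge[i], W_um - edge[i])
      y <- runif(1, edge[i], H_um - edge[i])
      if (i == 1L ||
          all((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2 >=
              (r_excl[seq_len(i - 1)] + r_excl[i] + separation_um)^2)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("infeasible packing: could not place organoid ", i, " of ", n,
           " after ", max_tries, " tries; requested density exceeds the ",
           sprintf("~%.0f organoids this %.0f x %.0f um field can hold",
                   0.55 * (H_um * W_um) / (pi * mean(2 * r_excl)^2 / 2),
                   W_um, H_um))
  }
  cbind(cx = cx, cy = cy)
}

# render every (frame, z) mosaic for one condition and cut it into tiles
render_condition <- function(config, ctr, radius_t, ring, focal_plane,
                             visible, illum_theta) {
  geom <- config$geometry
  px <- geom$pixel_size_um
  msh <- mosaic_shape(geom)
  lv <- config$levels # background, lumen, ring
  n <- nrow(ctr)

  xs <- (seq_len(msh[2]) - 1) * px
  ys <- (seq_len(msh[1]) - 1) * px
  illum <- 1 + config$illumination_gradient_amplitude *
    (outer(rep(1, msh[1]), xs / max(xs) - 0.5) * cos(illum_theta) +
     outer(ys / max(ys) - 0.5, rep(1, msh[2])) * sin(illum_theta))

  org <- tile_origins(geom)
  th <- geom$tile_shape_px[1]; tw <- geom$tile_shape_px[2]
  tiles <- replicate(nrow(org),
                     array(0, dim = c(th, tw, geom$z_planes, geom$n_frames)),
                     simplify = FALSE)
  sig_z <- function(i, iz)
    config$base_blur_px +
      config$defocus_px_per_um * geom$z_spacing_um * abs(iz - focal_plane[i])

  for (f in seq_len(geom$n_frames)) {
    # per-organoid pixel boxes and radial distances, shared across z
    boxes <- vector("list", n)
    for (i in seq_len(n)) {
      if (!visible[i, f]) next
      ro_px <- (radius_t[i, f] + ring) / px
      smax <- sig_z(i, 1) + config$defocus_px_per_um * geom$z_spacing_um *
        geom$z_planes
      half <- ceiling(ro_px + 3 * smax + 2)
      ic <- ctr[i, 2] / px + 1 # row (y), 1-based fractional
      jc <- ctr[i, 1] / px + 1
      rr <- max(1, floor(ic - half)):min(msh[1], ceiling(ic + half))
      cc <- max(1, floor(jc - half)):min(msh[2], ceiling(jc + half))
      d <- sqrt(outer((rr - ic)^2, (cc - jc)^2, "+"))
      boxes[[i]] <- list(rr = rr, cc = cc, d = d)
    }
    for (iz in seq_len(geom$z_planes)) {
      mos <- matrix(lv[1], msh[1], msh[2])
      for (i in seq_len(n)) {
        if (!visible[i, f]) next
        b <- boxes[[i]]
        s <- sig_z(i, iz)
        rl_px <- radius_t[i, f] / px
        ro_px <- (radius_t[i, f] + ring) / px
        inner <- pnorm((rl_px - b$d) / s)
        outer_ <- pnorm((ro_px - b$d) / s)
        mos[b$rr, b$cc] <- mos[b$rr, b$cc] +
          (lv[2] - lv[1]) * inner + (lv[3] - lv[1]) * (outer_ - inner)
      }
      mos <- mos * illum
      for (k in seq_len(nrow(org))) {
        sub <- mos[org$y0[k] + seq_len(th), org$x0[k] + seq_len(tw)]
        if (config$noise_sd > 0)
          sub <- sub + matrix(rnorm(th * tw, sd = config$noise_sd), th, tw)
        tiles[[k]][, , iz, f] <- pmin(pmax(sub, 0), 1)
      }
    }
  }
  list(tiles = tiles, tile_grid = org[, c("row", "col")])
}

#' Write / read a ground-truth table
#'
#' Plain-CSV round trip of the simulator's per-organoid, per-frame table.
#'
#' @param gt ground-truth data frame (see [simulate_recording()]).
#' @param path file path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(gt, path) {
  cols <- c("organoid_id", "condition", "frame", "cx_um", "cy_um",
            "lumen_radius_um", "true_lumen_area_um2", "visible")
  if (nrow(gt) == 0) {
    gt <- data.frame(organoid_id = integer(), condition = character(),
                     frame = integer(), cx_um = numeric(),
                     cy_um = numeric(), lumen_radius_um = numeric(),
                     true_lumen_area_um2 = numeric(), visible = logical())
  } else stopifnot(all(cols %in% names(gt)))
  write.csv(gt[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- read.csv(path, colClasses = c(
    organoid_id = "integer", condition = "character", frame = "integer",
    cx_um = "numeric", cy_um = "numeric", lumen_radius_um = "numeric",
    true_lumen_area_um2 = "numeric", visible = "logical"
  ))
  gt
}
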