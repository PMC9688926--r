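#' End-to-end pipeline configuration
#'
#' Bundles the per-stage parameter blocks, the analysis options and the
#' seed. All blocks validate at construction time, before any stage runs.
#'
#' @param simulation a [simulation_config()].
#' @param segmentation a [segmentation_params()].
#' @param linking a [linking_params()].
#' @param window NPA baseline window (frames).
#' @param reference reference condition of the relative-size table
#'   (defaults to the first condition).
#' @param dose_pair optional `c(high, low)` condition names.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            segmentation = segmentation_params(),
                            linking = linking_params(),
                            window = 5L, reference = NULL,
                            dose_pair = NULL) {
  stopifnot(inherits(simulation, "simulation_config"),
            inherits(segmentation, "segmentation_params"),
            inherits(linking, "linking_params"),
            window >= 1)
  if (is.null(reference)) reference <- names(simulation$conditions)[1]
  stopifnot(reference %in% names(simulation$conditions))
  structure(list(simulation = simulation, segmentation = segmentation,
                 linking = linking, window = as.integer(window),
                 reference = reference, dose_pair = dose_pair),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The file mirrors the configuration field names; `load -> save -> load`
#' round-trips identically.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), unclass, how = "replace")
  plain$simulation$geometry <- unclass(config$simulation$geometry)
  plain$simulation$conditions <- as.list(config$simulation$conditions)
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- do.call(acquisition_geometry, y$simulation$geometry)
  sim_args <- y$simulation
  sim_args$geometry <- geom
  sim_args$conditions <- unlist(y$simulation$conditions)
  sim_args$initial_radius_um <- unlist(sim_args$initial_radius_um)
  sim_args$levels <- unlist(sim_args$levels)
  pipeline_config(
    simulation = do.call(simulation_config, sim_args),
    segmentation = do.call(segmentation_params, y$segmentation),
    linking = do.call(linking_params, y$linking),
    window = y$window, reference = y$reference,
    dose_pair = if (length(y$dose_pair)) unlist(y$dose_pair) else NULL
  )
}

#' Write / read a tiled z-stack recording as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per tile (`tile_r<r>_c<c>.tif`, page order:
#' z-plane fastest within each frame) plus a `geometry.json` sidecar.
#' Intensities on the `[0, 1]` scale are quantized to 16 bits on write.
#'
#' @param recording list with `tiles` (list of `h x w x z x frame` arrays in
#'   row-major grid order) and `geometry`.
#' @param dir output directory (created if needed).
#' @return `write_image_stack()` returns `dir` invisibly;
#'   `read_image_stack()` returns a recording list (`tiles`, `geometry`,
#'   `condition = NA`).
#' @export
write_image_stack <- function(recording, dir) {
  geom <- recording$geometry
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  org <- tile_origins(geom)
  stopifnot(length(recording$tiles) == nrow(org))
  for (k in seq_len(nrow(org))) {
    pages <- list()
    a <- recording$tiles[[k]]
    for (f in seq_len(geom$n_frames))
      for (z in seq_len(geom$z_planes))
        pages[[length(pages) + 1L]] <- a[, , z, f]
    tiff::writeTIFF(pages,
                    file.path(dir, sprintf("tile_r%d_c%d.tif",
                                           org$row[k], org$col[k])),
                    bits.per.sample = 16L)
  }
  jsonlite::write_json(unclass(geom), file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_image_stack
#' @param geometry an [acquisition_geometry()]; when `NULL`, the
#'   `geometry.json` sidecar is required.
#' @export
read_image_stack <- function(dir, geometry = NULL) {
  if (is.null(geometry)) {
    gj <- file.path(dir, "geometry.json")
    if (!file.exists(gj))
      stop("no geometry.json sidecar in ", dir,
           "; pass `geometry` explicitly")
    y <- jsonlite::read_json(gj, simplifyVector = TRUE)
    geometry <- do.call(acquisition_geometry, y)
  }
  org <- tile_origins(geometry)
  tiles <- vector("list", nrow(org))
  for (k in seq_len(nrow(org))) {
    path <- file.path(dir, sprintf("tile_r%d_c%d.tif",
                                   org$row[k], org$col[k]))
    if (!file.exists(path)) stop("missing tile image: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != geometry$n_frames * geometry$z_planes)
      stop("page count (", length(pages), ") does not match frames x ",
           "z-planes (", geometry$n_frames * geometry$z_planes, ") in ",
           path)
    a <- array(0, dim = c(geometry$tile_shape_px,
                          geometry$z_planes, geometry$n_frames))
    p <- 1L
    for (f in seq_len(geometry$n_frames))
      for (z in seq_len(geometry$z_planes)) {
        a[, , z, f] <- pages[[p]]
        p <- p + 1L
      }
    tiles[[k]] <- a
  }
  list(tiles = tiles, geometry = geometry, condition = NA_character_)
}

#' Run the organoid growth analysis pipeline
#'
#' Executes simulate -> project/stitch -> segment -> measure -> track ->
#' analyze -> stats on every condition of the configuration and writes the
#' stage outputs (CSV tables, optional TIFFs, a JSON manifest) to
#' `out_dir`. The analysis can also start from a pre-measured tracks table
#' via `tracks_csv`, skipping all imaging stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @param write_images also write the simulated recordings and label masks
#'   as TIFFs (off by default; the tables are the analysis surface).
#' @param tracks_csv optional path of a tracks CSV with columns
#'   `organoid_id`, `condition`, `frame`, `area_um2`; when given, the
#'   imaging stages are skipped.
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with `tracks` (per condition), `curves`,
#'   `summaries`, `table` (the relative-size table), `stats` (data frame)
#'   and `ground_truth` (when simulated).
#' @export
run_pipeline <- function(config, out_dir, write_images = FALSE,
                         tracks_csv = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  px <- config$simulation$geometry$pixel_size_um
  gt <- NULL

  if (is.null(tracks_csv)) {
    say("simulate: %d organoids x %d condition(s), seed %d",
        config$simulation$n_organoids,
        length(config$simulation$conditions), config$simulation$seed)
    sim <- simulate_recording(config$simulation)
    gt <- sim$ground_truth
    write_ground_truth(gt, file.path(out_dir, "ground_truth.csv"))

    all_entries <- list()
    all_regions <- list()
    tracks_by_cond <- list()
    for (cond in names(sim$recordings)) {
      rec <- sim$recordings[[cond]]
      if (write_images)
        write_image_stack(rec, file.path(out_dir, paste0("raw_", cond)))
      say("preprocess [%s]: z-projection + stitching, %d frames", cond,
          rec$geometry$n_frames)
      mosaics <- project_and_stitch(rec)
      say("segment [%s]: marker-controlled watershed", cond)
      labs <- segment_frames(mosaics, config$segmentation, px)
      regions <- measure_frames(labs, px)
      regions$condition <- cond
      all_regions[[cond]] <- regions
      say("track [%s]: %d regions linked", cond, nrow(regions))
      tr <- link_frames(labs, regions, config$linking)
      say("track [%s]: %d tracks, %d complete, %d excluded", cond,
          nrow(tr$summary), sum(tr$summary$complete),
          sum(!tr$summary$complete))
      tracks_by_cond[[cond]] <- tr
      e <- tr$entries
      e$condition <- cond
      all_entries[[cond]] <- e
      rm(mosaics, labs, regions); gc(FALSE)
    }
    entries <- do.call(rbind, c(all_entries, list(make.row.names = FALSE)))
    write.csv(entries, file.path(out_dir, "tracks.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, c(all_regions, list(make.row.names = FALSE))),
              file.path(out_dir, "regions.csv"), row.names = FALSE)
  } else {
    say("loading tracks from %s (imaging stages skipped)", tracks_csv)
    entries <- read.csv(tracks_csv)
    stopifnot(all(c("organoid_id", "condition", "frame", "area_um2")
                  %in% names(entries)))
    if (!"missing" %in% names(entries))
      entries$missing <- is.na(entries$area_um2)
    tracks_by_cond <- split(entries, entries$condition)
    nf <- max(entries$frame)
    tracks_by_cond <- lapply(tracks_by_cond, function(e) {
      ids <- unique(e$organoid_id)
      s <- data.frame(
        organoid_id = ids,
        first_frame = vapply(ids, function(i)
          min(e$frame[e$organoid_id == i]), numeric(1)),
        n_detected = vapply(ids, function(i)
          sum(!e$missing[e$organoid_id == i]), numeric(1)))
      s$complete <- s$n_detected == nf
      structure(list(entries = e, summary = s, n_frames = nf),
                class = "organoid_tracks")
    })
  }

  say("analyze: NPA (baseline window %d), condition medians",
      config$window)
  curves <- list(); summaries <- list()
  for (cond in names(tracks_by_cond)) {
    cv <- npa_curves(tracks_by_cond[[cond]], config$window,
                     condition = cond)
    if (!length(cv)) {
      say("analyze [%s]: no complete tracks, skipped", cond)
      next
    }
    curves[[cond]] <- cv
    summaries[[cond]] <- condition_median_curve(cv)
  }
  npa_df <- do.call(rbind, lapply(unlist(curves, recursive = FALSE),
    function(cv) data.frame(organoid_id = cv$organoid_id,
                            condition = cv$condition,
                            frame = seq_along(cv$npa), npa = cv$npa)))
  write.csv(npa_df, file.path(out_dir, "npa.csv"), row.names = FALSE)
  med_df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(condition = s$condition,
               frame = seq_along(s$median_npa),
               median_npa = s$median_npa)))
  write.csv(med_df, file.path(out_dir, "median_curves.csv"),
            row.names = FALSE)

  tab <- relative_size_table(summaries, config$reference,
                             config$dose_pair)
  write.csv(tab, file.path(out_dir, "relative_sizes.csv"),
            row.names = FALSE)

  say("stats: Mann-Whitney on median NPA series vs '%s'",
      config$reference)
  stats_rows <- list()
  ref_med <- summaries[[config$reference]]$median_npa
  for (cond in setdiff(names(summaries), config$reference)) {
    mw <- mann_whitney_u(summaries[[cond]]$median_npa, ref_med)
    stats_rows[[cond]] <- data.frame(
      test = "mann_whitney_u", group1 = cond, group2 = config$reference,
      n1 = length(summaries[[cond]]$median_npa), n2 = length(ref_med),
      statistic = mw$statistic, p_value = mw$p_value,
      stars = trimws(significance_stars(mw$p_value)),
      note = "time points treated as observations; serial autocorrelation not corrected")
  }
  stats_df <- if (length(stats_rows))
    do.call(rbind, c(stats_rows, list(make.row.names = FALSE))) else
    data.frame()
  write.csv(stats_df, file.path(out_dir, "stats.csv"), row.names = FALSE)

  manifest <- list(
    package = "orgatrack",
    version = as.character(utils::packageVersion("orgatrack")),
    seed = config$simulation$seed,
    conditions = as.list(config$simulation$conditions),
    reference = config$reference,
    window = config$window,
    n_frames = config$simulation$geometry$n_frames,
    excluded_tracks = lapply(tracks_by_cond, function(tr)
      sum(!tr$summary$complete)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s", manifest$elapsed_s)
  invisible(list(tracks = tracks_by_cond, curves = curves,
                 summaries = summaries, table = tab, stats = stats_df,
                 ground_truth = gt))
}
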