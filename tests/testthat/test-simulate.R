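test_that("ground-truth areas follow the exponential growth law", {
  g <- log(2.3) / 48
  cfg <- simulation_config(
    geometry = tiny_geometry(n_frames = 5L),
    n_organoids = 3, conditions = c(a = 0, b = 0.5),
    base_growth_rate_per_h = g, seed = 2)
  # 5 frames at 0.5 h span 2 h; check the ratio against the closed form
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth
  for (cond in c("a", "b")) {
    eta <- cfg$conditions[[cond]]
    for (id in unique(gt$organoid_id)) {
      a <- gt[gt$condition == cond & gt$organoid_id == id, ]
      ratio <- a$true_lumen_area_um2[5] / a$true_lumen_area_um2[1]
      expect_equal(ratio, exp(g * (1 - eta) * 2), tolerance = 1e-12)
      # log-area linear in t, and radii non-decreasing
      expect_true(all(diff(a$lumen_radius_um) >= 0))
      expect_equal(pi * a$lumen_radius_um^2, a$true_lumen_area_um2)
    }
  }
})

test_that("a 48 h recording at 0.5 h interval emits 97 frames", {
  cfg <- simulation_config(
    geometry = acquisition_geometry(tile_rows = 1, tile_cols = 1,
                                    z_planes = 1,
                                    n_frames = frame_count(48, 0.5),
                                    tile_shape_px = c(64L, 64L)),
    n_organoids = 1, initial_radius_um = c(6, 0), noise_sd = 0, seed = 1)
  sim <- simulate_recording(cfg)
  expect_equal(dim(sim$recordings$untreated$tiles[[1]])[4], 97L)
  expect_equal(max(sim$ground_truth$frame), 97L)
})

test_that("half-inhibition yields the square-root area ratio", {
  # exp(g (1-0.5) 48) = 2.3^0.5 with g = ln(2.3)/48
  expect_equal(exp((log(2.3) / 48) * 0.5 * 48), sqrt(2.3),
               tolerance = 1e-12)
  cfg <- simulation_config(
    geometry = tiny_geometry(n_frames = 97L, z_planes = 1L,
                             shape = c(128L, 128L)),
    n_organoids = 1, conditions = c(t = 0.5),
    initial_radius_um = c(10, 0), noise_sd = 0, seed = 3)
  gt <- simulate_recording(cfg)$ground_truth
  expect_equal(gt$true_lumen_area_um2[97] / gt$true_lumen_area_um2[1],
               sqrt(2.3), tolerance = 1e-9)
})

test_that("identical seeds reproduce images and ground truth bit-exactly", {
  cfg <- tiny_sim_config(seed = 9, noise_sd = 0.02, n_frames = 2L)
  s1 <- simulate_recording(cfg)
  s2 <- simulate_recording(cfg)
  expect_identical(s1$recordings$untreated$tiles,
                   s2$recordings$untreated$tiles)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_recording(tiny_sim_config(seed = 10, noise_sd = 0.02,
                                           n_frames = 2L))
  expect_false(identical(s1$recordings$untreated$tiles,
                         s3$recordings$untreated$tiles))
})

test_that("dropout frames are flagged invisible and not rendered", {
  cfg <- tiny_sim_config(seed = 4, n_organoids = 2, n_frames = 8L,
                         dropout = 0.3)
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth
  expect_true(any(!gt$visible)) # at this rate some dropout occurs
  # an invisible organoid leaves the scene: compare a dropout frame with a
  # visible frame at the organoid's location
  inv <- gt[!gt$visible, ][1, ]
  vis <- gt[gt$visible & gt$organoid_id == inv$organoid_id, ][1, ]
  px <- cfg$geometry$pixel_size_um
  tile <- sim$recordings$untreated$tiles[[1]]
  i <- round(inv$cy_um / px) + 1; j <- round(inv$cx_um / px) + 1
  lumen_when_visible <- tile[i, j, 1, vis$frame]
  lumen_when_dropped <- tile[i, j, 1, inv$frame]
  expect_gt(lumen_when_visible, lumen_when_dropped + 0.1)
})

test_that("infeasible packing raises an error naming the density limit", {
  cfg <- simulation_config(
    geometry = tiny_geometry(n_frames = 1L, z_planes = 1L,
                             shape = c(96L, 96L)),
    n_organoids = 60, initial_radius_um = c(15, 0.1),
    max_place_tries = 200L, seed = 1)
  expect_error(simulate_recording(cfg), "packing|density|field")
})

test_that("default configuration stays inside the observed culture density", {
  cfg <- simulation_config()
  expect_gte(cfg$n_organoids, 41)
  expect_lte(cfg$n_organoids, 139)
})

test_that("rendered in-focus lumen pixel count matches the disk area to a perimeter bound", {
  cfg <- tiny_sim_config(seed = 6, n_organoids = 1, n_frames = 1L,
                         noise_sd = 0, initial_radius_um = c(25, 0),
                         shape = c(200L, 200L))
  sim <- simulate_recording(cfg)
  img <- sim$recordings$untreated$tiles[[1]][, , 1, 1]
  lv <- cfg$levels # background, lumen, ring
  r_px <- 25 / cfg$geometry$pixel_size_um
  count <- sum(img > (lv[1] + lv[2]) / 2)
  expect_lt(abs(count - pi * r_px^2), 2 * pi * r_px + 8)
})

test_that("ground-truth tables round-trip through CSV", {
  cfg <- tiny_sim_config(seed = 8, n_organoids = 2, n_frames = 3L)
  gt <- simulate_recording(cfg)$ground_truth
  expect_equal(nrow(gt), 2 * 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(gt, path)
  back <- read_ground_truth(path)
  expect_identical(back$organoid_id, gt$organoid_id)
  expect_identical(back$frame, gt$frame)
  expect_identical(back$visible, gt$visible)
  expect_equal(back$true_lumen_area_um2, gt$true_lumen_area_um2,
               tolerance = 1e-12)
  # empty table -> header-only file
  write_ground_truth(gt[0, ], path)
  expect_equal(nrow(read_ground_truth(path)), 0)
  expect_equal(length(readLines(path)), 1L)
})
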