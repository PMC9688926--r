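test_that("morphological gradient matches hand-evaluated toys", {
  expect_equal(morphological_gradient(matrix(3.7, 6, 6), 2),
               matrix(0, 6, 6))
  # 1D step 0|9, disk radius 1: gradient 9 at the two step-adjacent pixels
  row <- matrix(c(0, 0, 0, 9, 9, 9), nrow = 1)
  expect_equal(morphological_gradient(row, 1),
               matrix(c(0, 0, 9, 9, 0, 0), nrow = 1))
  # invariance to additive constants
  img <- smooth_random_image(9, 9, seed = 3)
  expect_equal(morphological_gradient(img + 5, 2),
               morphological_gradient(img, 2), tolerance = 1e-12)
  expect_true(all(morphological_gradient(img, 2) >= 0))
})

test_that("extended minima match hand-evaluated basins", {
  # strictly monotone ramp: one regional minimum whatever h
  ramp <- outer(1:6, 1:6, function(i, j) i + 10 * j)
  expect_equal(max(extended_minima_markers(ramp, h = 2)), 1)
  # two depth-5 basins separated by a ridge
  g <- matrix(5, 5, 5); g[2:4, 2] <- 0; g[2:4, 4] <- 0
  expect_equal(max(extended_minima_markers(g, h = 1)), 2)
  expect_equal(max(extended_minima_markers(g, h = 6)), 1)
  # h = 0 reduces to plain regional minima
  img <- smooth_random_image(10, 10, seed = 5)
  expect_equal(extended_minima_markers(img, h = 0),
               orgatrack:::.cpp_regional_minima(img, 4L))
})

test_that("watershed floods the 5x5 two-basin toy as hand-derived", {
  im <- matrix(9, 5, 5); im[, 1:2] <- 0; im[, 4:5] <- 1
  mk <- matrix(0L, 5, 5); mk[3, 1] <- 1L; mk[3, 5] <- 2L
  ws <- watershed_from_markers(im, mk, 4)
  expect_equal(sum(ws$labels == 1), 10)
  expect_equal(sum(ws$labels == 2), 10)
  expect_true(all(ws$labels[, 3] == 0)) # ridge = watershed line
})

test_that("a single marker floods the whole image without lines", {
  img <- smooth_random_image(8, 8, seed = 11)
  mk <- matrix(0L, 8, 8); mk[4, 4] <- 1L
  ws <- watershed_from_markers(img, mk, 4)
  expect_true(all(ws$labels == 1))
})

test_that("watershed result is invariant to marker label permutation", {
  img <- smooth_random_image(10, 10, seed = 17)
  mk <- extended_minima_markers(img, h = 0.05)
  ws1 <- watershed_from_markers(img, mk, 4)$labels
  perm <- rev(seq_len(max(mk)))
  mk2 <- mk; mk2[mk > 0] <- perm[mk[mk > 0]]
  ws2 <- watershed_from_markers(img, mk2, 4)$labels
  expect_identical(ws1 > 0, ws2 > 0)
  expect_identical(perm[ws1[ws1 > 0]], ws2[ws1 > 0])
})

test_that("watershed equals the brute-force priority-flood oracle on small fixtures", {
  cases <- expand.grid(seed = 1:10, conn = c(4L, 8L))
  for (k in seq_len(nrow(cases))) {
    nr <- 5 + (cases$seed[k] %% 8)  # 5..12
    nc <- 12 - (cases$seed[k] %% 6) # 7..12
    img <- round(smooth_random_image(nr, nc, seed = 100 + cases$seed[k]), 2)
    mk <- extended_minima_markers(img, h = 0.05,
                                  connectivity = cases$conn[k])
    if (!any(mk > 0)) next
    ws <- watershed_from_markers(img, mk, cases$conn[k])$labels
    expect_identical(ws, flood_oracle(img, mk, cases$conn[k]),
                     label = sprintf("oracle case seed=%d conn=%d",
                                     cases$seed[k], cases$conn[k]))
  }
})

test_that("regions plus background/lines partition the frame", {
  img <- smooth_random_image(30, 30, seed = 23)
  mk <- extended_minima_markers(img, h = 0.02)
  ws <- watershed_from_markers(img, mk, 4)$labels
  expect_equal(sum(tabulate(ws[ws > 0])) + sum(ws == 0), 900)
})

test_that("marker count is non-increasing in h and object count in min_area", {
  img <- smooth_random_image(40, 40, seed = 29)
  hs <- c(0, 0.01, 0.05, 0.1, 0.3)
  counts <- vapply(hs, function(h)
    max(extended_minima_markers(img, h)), numeric(1))
  expect_true(all(diff(counts) <= 0))

  cfg <- tiny_sim_config(seed = 12, n_organoids = 4, n_frames = 1L)
  sim <- simulate_recording(cfg)
  mos <- project_and_stitch(sim$recordings$untreated)[[1]]
  px <- cfg$geometry$pixel_size_um
  n_at <- vapply(c(100, 500, 1200, 1e5), function(a)
    segment_frame(mos, segmentation_params(min_area_um2 = a),
                  px)$n_objects, numeric(1))
  expect_true(all(diff(n_at) <= 0))
  expect_equal(n_at[4], 0) # filter above the largest organoid
})

test_that("noise-free frames with isolated organoids are recovered near their true areas", {
  cfg <- tiny_sim_config(seed = 14, n_organoids = 3, n_frames = 1L,
                         noise_sd = 0, initial_radius_um = c(45, 0.05),
                         shape = c(420L, 420L))
  sim <- simulate_recording(cfg)
  mos <- project_and_stitch(sim$recordings$untreated)[[1]]
  px <- cfg$geometry$pixel_size_um
  lf <- segment_frame(mos, segmentation_params(), px)
  expect_equal(lf$n_objects, 3)
  reg <- measure_regions(lf, px)
  gt <- sim$ground_truth
  # match by centroid, compare areas (watershed-line annulus allows ~5%)
  for (i in seq_len(3)) {
    d <- sqrt((reg$cx_um - gt$cx_um[i])^2 + (reg$cy_um - gt$cy_um[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 5)
    expect_lt(abs(reg$area_um2[j] - gt$true_lumen_area_um2[i]) /
                gt$true_lumen_area_um2[i], 0.05)
  }
})

test_that("blank frames yield an empty labeling, not an error", {
  lf <- segment_frame(matrix(0.5, 60, 60), segmentation_params(), 1.29)
  expect_equal(lf$n_objects, 0)
  expect_true(all(lf$labels == 0))
})

test_that("surviving labels are consecutive and ordered by descending area", {
  cfg <- tiny_sim_config(seed = 16, n_organoids = 5, n_frames = 1L,
                         initial_radius_um = c(18, 0.25),
                         shape = c(300L, 300L))
  sim <- simulate_recording(cfg)
  mos <- project_and_stitch(sim$recordings$untreated)[[1]]
  px <- cfg$geometry$pixel_size_um
  lf <- segment_frame(mos, segmentation_params(min_area_um2 = 250), px)
  expect_gt(lf$n_objects, 1)
  expect_setequal(unique(as.vector(lf$labels[lf$labels > 0])),
                  seq_len(lf$n_objects))
  areas <- tabulate(lf$labels[lf$labels > 0])
  expect_true(all(diff(areas) <= 0))
})
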