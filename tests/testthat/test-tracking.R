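# build labeled_frame objects directly from label matrices
lf_list <- function(mats) lapply(seq_along(mats), function(f)
  orgatrack:::labeled_frame(mats[[f]], frame = f))

disk_at <- function(m, ci, cj, r, lab) {
  d2 <- outer((seq_len(nrow(m)) - ci)^2, (seq_len(ncol(m)) - cj)^2, "+")
  m[d2 <= r^2] <- lab
  m
}

test_that("stationary objects yield one complete track each with stable identity", {
  base <- matrix(0L, 60, 60)
  frames <- lapply(1:4, function(f) {
    m <- disk_at(base, 15, 15, 6 + f / 2, 1L)
    disk_at(m, 45, 40, 9, 2L)
  })
  tr <- link_frames(lf_list(frames), pixel_size_um = 1)
  expect_equal(nrow(tr$summary), 2)
  expect_true(all(tr$summary$complete))
  # identity: track 1 stays on the small disk as it grows
  e1 <- tr$entries[tr$entries$organoid_id == 1, ]
  expect_true(all(abs(e1$cy_um - 14) < 2))
})

test_that("an object missing in one frame yields an incomplete track that re-links", {
  base <- matrix(0L, 60, 60)
  with_obj <- disk_at(disk_at(base, 20, 20, 7, 1L), 45, 45, 6, 2L)
  without <- disk_at(base, 20, 20, 7, 1L)
  frames <- list(with_obj, with_obj, without, with_obj, with_obj)
  # relabel per frame arbitrarily: frame 4 swaps labels
  f4 <- matrix(0L, 60, 60)
  f4 <- disk_at(f4, 45, 45, 6, 1L); f4 <- disk_at(f4, 20, 20, 7, 2L)
  frames[[4]] <- f4
  tr <- link_frames(lf_list(frames), pixel_size_um = 1)
  expect_equal(nrow(tr$summary), 2)
  s <- tr$summary[order(tr$summary$organoid_id), ]
  expect_equal(sort(s$n_detected), c(4L, 5L))
  expect_equal(sum(s$complete), 1L)
  # the gap frame is recorded as MISSING and identity is re-acquired after it
  e2 <- tr$entries[tr$entries$organoid_id == 2, ]
  expect_true(e2$missing[e2$frame == 3])
  expect_false(e2$missing[e2$frame == 4])
  expect_lt(abs(e2$cy_um[e2$frame == 5] - e2$cy_um[e2$frame == 1]), 1)
})

test_that("the completeness filter keeps exactly the all-frame tracks", {
  base <- matrix(0L, 40, 40)
  a <- disk_at(base, 10, 10, 5, 1L)
  ab <- disk_at(a, 30, 30, 5, 2L)
  frames <- list(ab, a, ab)
  tr <- link_frames(lf_list(frames), pixel_size_um = 1)
  expect_equal(tr$summary$n_detected[order(tr$summary$organoid_id)],
               c(3L, 2L))
  kept <- filter_complete(tr)
  expect_equal(nrow(kept$summary), 1)
  expect_equal(kept$summary$organoid_id, 1L)
  all_complete <- filter_complete(link_frames(lf_list(list(ab, ab)),
                                              pixel_size_um = 1))
  expect_equal(nrow(all_complete$summary), 2)
  none <- filter_complete(tr, n_frames = 5)
  expect_equal(nrow(none$summary), 0)
})

test_that("linking is invariant to per-frame relabeling", {
  cfg <- tiny_sim_config(seed = 18, n_organoids = 4, n_frames = 3L)
  sim <- simulate_recording(cfg)
  px <- cfg$geometry$pixel_size_um
  labs <- segment_frames(project_and_stitch(sim$recordings$untreated),
                         segmentation_params(min_area_um2 = 250), px)
  tr1 <- link_frames(labs, pixel_size_um = px)
  # permute labels in every frame
  labs2 <- lapply(labs, function(lf) {
    k <- lf$n_objects
    if (k < 2) return(lf)
    perm <- rev(seq_len(k))
    m <- lf$labels
    m[lf$labels > 0] <- perm[lf$labels[lf$labels > 0]]
    orgatrack:::labeled_frame(m, lf$frame)
  })
  tr2 <- link_frames(labs2, pixel_size_um = px)
  c1 <- filter_complete(tr1); c2 <- filter_complete(tr2)
  expect_equal(nrow(c1$summary), nrow(c2$summary))
  # same set of area time-series regardless of labels
  key <- function(tr) {
    s <- split(round(tr$entries$area_um2, 6), tr$entries$organoid_id)
    unname(s[order(vapply(s, `[`, numeric(1), 1))])
  }
  expect_equal(key(c1), key(c2))
})

test_that("no two tracks share a region within a frame", {
  cfg <- tiny_sim_config(seed = 19, n_organoids = 5, n_frames = 4L,
                         dropout = 0.2, shape = c(300L, 300L))
  sim <- simulate_recording(cfg)
  px <- cfg$geometry$pixel_size_um
  labs <- segment_frames(project_and_stitch(sim$recordings$untreated),
                         segmentation_params(min_area_um2 = 250), px)
  tr <- link_frames(labs, pixel_size_um = px)
  e <- tr$entries[!tr$entries$missing, ]
  dup <- tapply(e$label, e$frame, anyDuplicated)
  expect_true(all(dup == 0))
})

test_that("zero-dropout simulations produce one complete track per organoid", {
  cfg <- tiny_sim_config(seed = 20, n_organoids = 6, n_frames = 4L,
                         shape = c(320L, 320L))
  sim <- simulate_recording(cfg)
  px <- cfg$geometry$pixel_size_um
  labs <- segment_frames(project_and_stitch(sim$recordings$untreated),
                         segmentation_params(min_area_um2 = 250), px)
  tr <- filter_complete(link_frames(labs, pixel_size_um = px))
  expect_equal(nrow(tr$summary), 6)
})
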