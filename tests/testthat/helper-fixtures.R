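# Shared small simulation fixtures, built in code at test time.

tiny_geometry <- function(n_frames = 2L, z_planes = 2L, tiles = c(1L, 1L),
                          shape = c(200L, 200L)) {
  acquisition_geometry(tile_rows = tiles[1], tile_cols = tiles[2],
                       z_planes = z_planes, n_frames = n_frames,
                       tile_shape_px = shape)
}

# a few well-separated organoids in a single-tile field, in focus, low noise
tiny_sim_config <- function(seed = 5L, n_organoids = 3L, n_frames = 2L,
                            noise_sd = 0, dropout = 0,
                            conditions = c(untreated = 0),
                            initial_radius_um = c(20, 0.1),
                            z_planes = 1L, shape = c(220L, 220L)) {
  simulation_config(
    geometry = tiny_geometry(n_frames = n_frames, z_planes = z_planes,
                             tiles = c(1L, 1L), shape = shape),
    n_organoids = n_organoids, conditions = conditions,
    initial_radius_um = initial_radius_um,
    noise_sd = noise_sd, dropout_prob_per_frame = dropout,
    illumination_gradient_amplitude = if (noise_sd == 0) 0 else 0.1,
    seed = seed)
}

# smooth random test image for oracle-equivalence fixtures: sum of a few
# seeded cosine waves, values in roughly [0, 1]
smooth_random_image <- function(nr, nc, seed) {
  set.seed(seed)
  img <- matrix(0, nr, nc)
  for (k in 1:3) {
    fy <- runif(1, 0.5, 2); fx <- runif(1, 0.5, 2)
    py <- runif(1, 0, 2 * pi); px <- runif(1, 0, 2 * pi)
    img <- img + outer(cos(2 * pi * fy * seq_len(nr) / nr + py),
                       cos(2 * pi * fx * seq_len(nc) / nc + px))
  }
  (img - min(img)) / diff(range(img))
}
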