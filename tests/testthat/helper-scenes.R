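# Small scene/image builders shared across test files.

# compact configuration that renders in well under a second
tiny_scene_config <- function(seed = 1L, ...) {
  scene_config(grid_shape = c(24L, 64L, 64L), seed = seed, ...)
}

# the reduced-resolution grid used for the heavier simulation studies
reduced_scene_config <- function(seed = 1L, ...) {
  scene_config(grid_shape = c(32L, 128L, 128L), seed = seed, ...)
}

# a deterministic two-population (dim background + bright blob) volume
two_population_image <- function(dims = c(4L, 16L, 16L), bright = 200, dim_bg = 10) {
  arr <- array(dim_bg, dims)
  zc <- seq_len(max(1, dims[1] %/% 2))
  arr[zc, seq_len(dims[2] %/% 2), seq_len(dims[3] %/% 2)] <- bright
  voxel_image(arr, spacing = c(0.2, 0.1, 0.1))
}

# image whose intensity equals its 0-based x index (for profile tests)
x_ramp_image <- function(dims = c(3L, 4L, 8L), spacing = c(0.2, 0.1, 0.1)) {
  arr <- array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims)
  voxel_image(arr, spacing = spacing)
}

# mean thresholded-Pearson r over seeded cells at one axial offset
mean_r_at_offset <- function(offset, seeds, cfg_fun = reduced_scene_config,
                             self_pair = FALSE) {
  mean(vapply(seeds, function(s) {
    cfg <- cfg_fun(seed = s)
    enz <- if (self_pair) {
      e <- enzyme_profile("X", 0)
      list(e, e)
    } else {
      list(enzyme_profile("A", 0), enzyme_profile("B", offset))
    }
    sc <- render_cell(cfg, enz)
    a <- sc$image$channels[[1]]; b <- sc$image$channels[[2]]
    ct <- costes_thresholds(a, b)
    thresholded_pearson(a, b, ct)$r
  }, numeric(1)))
}
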