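test_that("pearson matches its definition and rejects degenerate input", {
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(pearson(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_error(pearson(c(1, 2), c(1, 2, 3)), "lengths")
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  expect_error(pearson(1, 2), "at least 2")
})

test_that("pearson equals the two-pass oracle on random vectors", {
  for (i in 1:30) {
    withr::with_seed(300 + i, {
      n <- sample(c(10, 100, 5000), 1)
      a <- rnorm(n) * 10 + 50
      b <- 0.5 * a + rnorm(n) * 5
    })
    expect_equal(pearson(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
})

test_that("pearson is invariant under positive affine rescaling", {
  withr::with_seed(11, {
    a <- runif(200) * 100
    b <- runif(200) * 100
  })
  r0 <- pearson(a, b)
  expect_equal(pearson(3.7 * a + 12, b), r0, tolerance = 1e-12)
  expect_equal(pearson(a, 0.01 * b + 5), r0, tolerance = 1e-12)
})

test_that("thresholded pearson of a channel with itself is 1", {
  base <- two_population_image(c(4, 12, 12))
  withr::with_seed(30, arr <- array(rpois(length(base$data), base$data), dim(base$data)))
  a <- voxel_image(arr, base$spacing)
  ct <- costes_thresholds(a, a)
  expect_equal(thresholded_pearson(a, a, ct)$r, 1)
})

test_that("union and intersection signal policies are both available and differ", {
  cfg <- tiny_scene_config(seed = 21L)
  sc <- render_cell(cfg, list(enzyme_profile("A", 0), enzyme_profile("B", 0.4)))
  a <- sc$image$channels[[1]]; b <- sc$image$channels[[2]]
  ct <- costes_thresholds(a, b)
  t_or <- thresholded_pearson(a, b, ct, voxel_policy = "or")
  t_and <- thresholded_pearson(a, b, ct, voxel_policy = "and")
  expect_gt(t_or$n_voxels, t_and$n_voxels)
  expect_false(isTRUE(all.equal(t_or$r, t_and$r)))
  # reproducible under the same inputs
  expect_identical(t_or$r, thresholded_pearson(a, b, ct, voxel_policy = "or")$r)
})

test_that("nMDP reproduces the hand-worked example", {
  a <- voxel_image(array(c(0, 10, 20, 30), c(1, 2, 2)))
  b <- voxel_image(array(c(0, 30, 20, 10), c(1, 2, 2)))
  fg <- whole_image_roi(a)
  res <- nmdp_map(a, b, fg)
  expect_equal(as.vector(res$field), c(1, -1/3, 1/9, -1/3), tolerance = 1e-12)
  expect_equal(res$icorr, 0.5)
  expect_equal(res$inega_corr, 0.5)
  expect_identical(res$icorr + res$inega_corr, 1)
})

test_that("nMDP is 1 at the joint maximum and bounded above by 1", {
  withr::with_seed(31, arr_a <- array(sample(0:200, 4 * 6 * 6, TRUE), c(4, 6, 6)))
  withr::with_seed(32, arr_b <- array(sample(0:200, 4 * 6 * 6, TRUE), c(4, 6, 6)))
  # force a joint-maximum voxel
  arr_a[1, 1, 1] <- 255; arr_b[1, 1, 1] <- 255
  a <- voxel_image(arr_a); b <- voxel_image(arr_b)
  res <- nmdp_map(a, b, whole_image_roi(a))
  expect_equal(res$field[1, 1, 1], 1)
  expect_true(all(res$field[!is.na(res$field)] <= 1 + 1e-12))
})

test_that("Icorr is invariant under positive affine rescaling of a channel", {
  withr::with_seed(33, arr <- array(sample(0:100, 4 * 8 * 8, TRUE), c(4, 8, 8)))
  withr::with_seed(34, arr2 <- array(sample(0:100, 4 * 8 * 8, TRUE), c(4, 8, 8)))
  a <- voxel_image(arr); b <- voxel_image(arr2)
  fg <- whole_image_roi(a)
  i0 <- nmdp_map(a, b, fg)$icorr
  a2 <- voxel_image(2.5 * arr + 7)
  expect_equal(nmdp_map(a2, b, fg)$icorr, i0)
  expect_equal(nmdp_map(a, voxel_image(0.3 * arr2 + 1), fg)$icorr, i0)
})

test_that("Icorr of a channel against itself is 1 away from exact-mean voxels", {
  withr::with_seed(35, arr <- array(sample(0:100, 125, TRUE), c(5, 5, 5)))
  a <- voxel_image(arr)
  fg <- roi_mask(array(arr != mean(arr), dim(arr)))
  expect_equal(nmdp_map(a, a, fg)$icorr, 1)
})

test_that("nMDP rejects a channel constant over the foreground", {
  a <- voxel_image(array(5, c(2, 2, 2)))
  b <- voxel_image(array(runif(8), c(2, 2, 2)))
  expect_error(nmdp_map(a, b, whole_image_roi(a)), "constant")
})

test_that("segmented foreground excludes background and feeds nMDP", {
  a <- two_population_image(c(4, 12, 12), bright = 180, dim_bg = 8)
  withr::with_seed(36, {
    noise_a <- array(rpois(length(a$data), a$data), dim(a$data))
    noise_b <- array(rpois(length(a$data), a$data), dim(a$data))
  })
  a2 <- voxel_image(noise_a); b2 <- voxel_image(noise_b)
  fg <- segment_foreground(a2, b2, method = "otsu")
  expect_lt(sum(fg$data), length(fg$data))     # some background excluded
  res <- nmdp_map(a2, b2, fg)
  expect_equal(res$seg_method, "otsu")
  expect_identical(res$inega_corr, 1 - res$icorr)
  expect_equal(sum(!is.na(res$field)), sum(fg$data))
})

test_that("line profiles interpolate trilinearly and normalize per channel", {
  img <- x_ramp_image()   # intensity == x index, spacing dx = 0.1 um
  prof <- line_profile(img, p0 = c(0.2, 0.15, 0), p1 = c(0.2, 0.15, 0.7),
                       n_samples = 8)
  expect_equal(max(prof$intensity), 1)
  expect_equal(prof$raw_intensity, seq(0, 7), tolerance = 1e-12)
  expect_true(all(diff(prof$position_um) > 0))

  # midpoint between voxels of values 10 and 20 interpolates to 15
  arr <- array(0, c(1, 1, 2)); arr[1, 1, 1] <- 10; arr[1, 1, 2] <- 20
  vi <- voxel_image(arr, spacing = c(1, 1, 1))
  mid <- line_profile(vi, c(0, 0, 0), c(0, 0, 1), n_samples = 3)
  expect_equal(mid$raw_intensity[2], 15)

  expect_error(line_profile(img, c(0, 0, 0), c(0, 0, 99)), "outside")
  expect_error(line_profile(img, c(0, 0, 0), c(0, 0, 0)), "coincide")
})

test_that("staggered axial peaks keep their ground-truth order in a profile", {
  cfg <- tiny_scene_config(seed = 41L, axis_jitter_deg = 0)
  mus <- c(-0.4, 0, 0.4)
  channels <- lapply(seq_along(mus), function(i) {
    noiseless <- scene_config(grid_shape = cfg$grid_shape, seed = 1L,
                              axis_jitter_deg = 0, shot_noise = FALSE,
                              read_noise_sd = 0, background = 0)
    sc <- render_cell(noiseless, list(enzyme_profile(paste0("E", i), mus[i]),
                                      enzyme_profile("ref", 0)))
    sc$image$channels[[1]]
  })
  img <- multi_channel_image(channels, "stack")
  ext <- (dim(channels[[1]]$data) - 1) * channels[[1]]$spacing
  # profile along z through the ribbon mid-point
  prof <- line_profile(img, c(0, ext[2] / 2, ext[3] / 2), c(ext[1], ext[2] / 2, ext[3] / 2),
                       n_samples = 200)
  peaks <- prof |>
    dplyr::group_by(channel) |>
    dplyr::summarise(peak = position_um[which.max(intensity)]) |>
    dplyr::arrange(match(channel, c("E1", "E2", "E3")))
  expect_true(all(diff(peaks$peak) > 0))
})

test_that("colocalize_pair composes the pipeline deterministically", {
  cfg <- tiny_scene_config(seed = 51L)
  sc <- render_cell(cfg, list(enzyme_profile("A", 0), enzyme_profile("B", 0.3)))
  res1 <- colocalize_pair(sc)
  res2 <- colocalize_pair(sc)
  expect_identical(res1$measurement, res2$measurement)
  expect_identical(res1$measurement$inega_corr, 1 - res1$measurement$icorr)
  expect_true(res1$measurement$costes_converged)

  scenes <- render_panel(cfg, list(enzyme_profile("A", 0), enzyme_profile("B", 0.3)),
                         n_cells = 2, base_seed = 7)
  batch <- colocalize_scenes(scenes)
  expect_equal(nrow(batch), length(scenes))
})
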