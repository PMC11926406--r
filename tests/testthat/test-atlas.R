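fake_measurements <- function(rbar, n_cells = 1) {
  labels <- rownames(rbar)
  rows <- list()
  for (i in seq_along(labels)) for (j in i:length(labels)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      label_a = labels[i], label_b = labels[j], r = rep(rbar[i, j], n_cells))
  }
  dplyr::bind_rows(rows)
}

test_that("distance matrix applies d = 1 - r with a zero diagonal", {
  rbar <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  D <- build_distance_matrix(fake_measurements(rbar))
  expect_equal(D$d["X", "Y"], 0)

  rbar[1, 2] <- rbar[2, 1] <- 0.4
  D <- build_distance_matrix(fake_measurements(rbar))
  expect_equal(D$d["X", "Y"], 0.6)
  expect_equal(diag(D$d), c(X = 0, Y = 0))
  expect_identical(D$d, t(D$d))
})

test_that("self-control normalization rescales by the dual-label ceiling", {
  rbar <- matrix(c(0.9, 0.6, 0.6, 0.8), 2, 2,
                 dimnames = list(c("X", "Y"), c("X", "Y")))
  D <- build_distance_matrix(fake_measurements(rbar), normalization = "self-control")
  expect_equal(D$d["X", "Y"], 1 - 0.6 / sqrt(0.9 * 0.8), tolerance = 1e-12)
  expect_equal(D$d["X", "Y"], 0.29289, tolerance = 1e-4)
  expect_equal(diag(D$d), c(X = 0, Y = 0))

  # normalized r is capped at 1 so distances stay non-negative
  rbar2 <- matrix(c(0.5, 0.9, 0.9, 0.5), 2, 2,
                  dimnames = list(c("X", "Y"), c("X", "Y")))
  D2 <- build_distance_matrix(fake_measurements(rbar2), normalization = "self-control")
  expect_gte(min(D2$d), 0)
})

test_that("incomplete designs are rejected with the offending pair named", {
  m <- tibble::tibble(label_a = c("X", "Y"), label_b = c("X", "Y"), r = c(0.9, 0.9))
  expect_error(build_distance_matrix(m), "X vs Y")
  m2 <- tibble::tibble(label_a = "X", label_b = "Y", r = 0.5)
  expect_error(build_distance_matrix(m2, normalization = "self-control"), "self-pair")
})

test_that("both measurement orders of a pair are averaged", {
  m <- tibble::tibble(label_a = c("X", "Y", "X", "Y"),
                      label_b = c("Y", "X", "X", "Y"),
                      r = c(0.6, 0.8, 1, 1))
  D <- build_distance_matrix(m)
  expect_equal(D$d["X", "Y"], 1 - 0.7)
})

test_that("SMACOF embeds coincident labels at the same point", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  emb <- mds_embed(d, seed = 2)
  expect_lt(sqrt(sum((emb$coords["a", ] - emb$coords["b", ])^2)), 1e-6)
})

test_that("an equilateral dissimilarity embeds with unit pairwise distances", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  emb <- mds_embed(d, seed = 3)
  dm <- as.matrix(dist(emb$coords))
  expect_equal(dm[upper.tri(dm)], rep(1, 3), tolerance = 1e-3)
})

test_that("exactly Euclidean distances are reproduced at near-zero stress", {
  withr::with_seed(71, pts <- matrix(rnorm(15), 5, 3))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:5)
  emb <- mds_embed(d, seed = 4)
  expect_lte(emb$stress, 1e-6)
  expect_equal(as.matrix(dist(emb$coords))[upper.tri(d)], d[upper.tri(d)],
               tolerance = 1e-3)
  # classical scaling as an independent oracle reproduces the same distances
  cmd <- cmdscale(d, k = 3)
  expect_equal(as.matrix(dist(emb$coords))[upper.tri(d)],
               as.matrix(dist(cmd))[upper.tri(d)], tolerance = 1e-3)
})

test_that("stress is non-increasing across SMACOF iterations", {
  withr::with_seed(72, {
    r <- matrix(runif(36, 0.2, 0.9), 6, 6)
  })
  d <- 1 - (r + t(r)) / 2
  diag(d) <- 0
  emb <- mds_embed(d, seed = 5, n_restarts = 2)
  expect_true(all(diff(emb$stress_trace) <= 1e-12))
})

test_that("MDS is deterministic given a seed and needs >= 3 labels", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(mds_embed(d), "at least 3")
  d3 <- matrix(1, 4, 4); diag(d3) <- 0
  e1 <- mds_embed(d3, seed = 9)
  e2 <- mds_embed(d3, seed = 9)
  expect_identical(e1$coords, e2$coords)
})

test_that("PCA projection matches a dense eigen-decomposition oracle", {
  for (i in 1:20) {
    withr::with_seed(800 + i, X <- matrix(rnorm(30), 10, 3) %*% diag(c(3, 1, 0.2)))
    got <- pca_project(X)
    want <- oracle_pca_2d(X)
    expect_equal(unname(got$coords2d), unname(want$coords2d), tolerance = 1e-9)
    expect_equal(got$explained_variance, want$explained_variance, tolerance = 1e-9)
  }
})

test_that("planar and collinear point sets give the expected variance split", {
  withr::with_seed(73, {
    plane <- cbind(rnorm(8), rnorm(8), 0)
  })
  got <- pca_project(plane)
  expect_equal(sum(got$explained_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(got$explained_variance) <= 1e-12))

  line <- cbind(1:6, 2 * (1:6), -0.5 * (1:6))
  got2 <- pca_project(line)
  expect_equal(got2$explained_variance[2], 0, tolerance = 1e-12)
  expect_error(pca_project(matrix(1, 1, 3)), "at least 2")
})

test_that("identically-distributed enzymes are mutually closest in the atlas", {
  # build a synthetic measurement table: twins at the same axial position,
  # a third enzyme clearly apart, noisy over cells
  withr::with_seed(74, {
    m <- dplyr::bind_rows(
      tibble::tibble(label_a = "T1", label_b = "T2", r = rnorm(8, 0.95, 0.01)),
      tibble::tibble(label_a = "T1", label_b = "Far", r = rnorm(8, 0.5, 0.02)),
      tibble::tibble(label_a = "T2", label_b = "Far", r = rnorm(8, 0.5, 0.02)),
      tibble::tibble(label_a = "T1", label_b = "T1", r = rnorm(8, 0.97, 0.01)),
      tibble::tibble(label_a = "T2", label_b = "T2", r = rnorm(8, 0.97, 0.01)),
      tibble::tibble(label_a = "Far", label_b = "Far", r = rnorm(8, 0.97, 0.01))
    )
  })
  atl <- make_atlas(m, seed = 11)
  td <- tidy(atl)
  xy <- as.matrix(td[, c("PC1", "PC2")])
  rownames(xy) <- td$label
  dm <- as.matrix(dist(xy))
  expect_equal(rownames(dm)[order(dm["T1", ])[2]], "T2")
  expect_equal(rownames(dm)[order(dm["T2", ])[2]], "T1")

  atl2 <- make_atlas(m, seed = 11)
  expect_identical(atl$coords2d, atl2$coords2d)

  g <- glance(atl)
  expect_equal(g$n_labels, 3)
  expect_s3_class(autoplot(atl), "ggplot")
})
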