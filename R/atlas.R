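#' Enzyme-enzyme dissimilarity matrix from colocalization measurements
#'
#' Averages per-cell Pearson `r` within each unordered enzyme pair (if both
#' orders were measured, the two directional means are averaged) and
#' converts to dissimilarity `d = 1 - rbar`. With
#' `normalization = "self-control"` each pair mean is first divided by the
#' geometric mean of the two dual-label self-pair means,
#' `rbar(X,Y) / sqrt(rbar(X,X) * rbar(Y,Y))`, capped at 1 — using the
#' same-enzyme two-fluorophore control as the attainable ceiling. The
#' diagonal is always 0.
#'
#' @param measurements tibble with columns `label_a`, `label_b`, `r` (one
#'   row per cell), e.g. from [colocalize_scenes()].
#' @param normalization `"none"` (default) or `"self-control"`.
#' @return An object of class `distance_matrix`: `labels`, `d` (symmetric
#'   matrix, zero diagonal), `r_mean` (the pair means used),
#'   `normalization`.
#' @export
build_distance_matrix <- function(measurements, normalization = c("none", "self-control")) {
  normalization <- match.arg(normalization)
  stopifnot(is.data.frame(measurements),
            all(c("label_a", "label_b", "r") %in% names(measurements)))
  directional <- measurements |>
    dplyr::group_by(.data$label_a, .data$label_b) |>
    dplyr::summarise(r = mean(.data$r), .groups = "drop")
  pairs <- directional |>
    dplyr::mutate(lo = pmin(.data$label_a, .data$label_b),
                  hi = pmax(.data$label_a, .data$label_b)) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(r = mean(.data$r), .groups = "drop")

  labels <- sort(unique(c(pairs$lo, pairs$hi)))
  k <- length(labels)
  rbar <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(nrow(pairs))) {
    rbar[pairs$lo[i], pairs$hi[i]] <- pairs$r[i]
    rbar[pairs$hi[i], pairs$lo[i]] <- pairs$r[i]
  }
  off <- which(upper.tri(rbar), arr.ind = TRUE)
  missing <- off[is.na(rbar[off]), , drop = FALSE]
  if (nrow(missing) > 0) {
    stop_input("missing measurement for pair(s): %s",
               paste(labels[missing[, 1]], labels[missing[, 2]],
                     sep = " vs ", collapse = ", "))
  }
  if (normalization == "self-control") {
    self <- diag(rbar)
    if (anyNA(self)) {
      stop_input("self-control normalization needs a self-pair for every enzyme")
    }
    if (any(self <= 0)) stop_input("self-pair mean r <= 0: self-control undefined")
    rbar <- pmin(rbar / sqrt(outer(self, self)), 1)
  }
  d <- 1 - rbar
  diag(d) <- 0
  structure(list(labels = labels, d = d, r_mean = rbar,
                 normalization = normalization),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d enzymes (d = 1 - mean r, normalization: %s)\n",
              length(x$labels), x$normalization))
  print(round(x$d, 4))
  invisible(x)
}

#' @export
tidy.distance_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$d, responseName = "distance",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(label_a = "Var1", label_b = "Var2")
}

# raw stress of a configuration against target dissimilarities
raw_stress <- function(delta, X) {
  dist_x <- as.matrix(stats::dist(X))
  sum((delta[upper.tri(delta)] - dist_x[upper.tri(dist_x)])^2)
}

smacof_once <- function(delta, n_dims, init, max_iter, tol) {
  n <- nrow(delta)
  X <- init
  dist_x <- as.matrix(stats::dist(X))
  stress <- sum((delta[upper.tri(delta)] - dist_x[upper.tri(dist_x)])^2)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # Guttman transform: X <- (1/n) B(X) X
    dx <- dist_x
    dx[dx == 0] <- Inf
    B <- -delta / dx
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- B %*% X / n
    dist_new <- as.matrix(stats::dist(X_new))
    stress_new <- sum((delta[upper.tri(delta)] - dist_new[upper.tri(dist_new)])^2)
    trace <- c(trace, stress_new)
    drop_ <- stress - stress_new
    X <- X_new
    dist_x <- dist_new
    stress <- stress_new
    if (drop_ < tol) break
  }
  list(X = X, stress = stress, iterations = it, trace = trace)
}

#' Metric MDS by SMACOF stress majorization
#'
#' Embeds a precomputed dissimilarity matrix into `n_dims` dimensions by
#' iterative stress majorization (Guttman transform) from seeded random
#' starts, keeping the lowest-stress solution. Stress is the raw residual
#' `sum_{i<j} (d_ij - delta_ij)^2` and is non-increasing across
#' iterations; iteration stops when the decrease falls below `tol` or
#' after `max_iter` iterations.
#'
#' @param D a [build_distance_matrix()] result (or plain symmetric matrix).
#' @param n_dims embedding dimension (default 3).
#' @param seed integer seed; restart `r` draws its start from
#'   `hash(seed, r)`.
#' @param n_restarts random restarts (default 8).
#' @param max_iter,tol convergence controls; the default stops when an
#'   iteration improves stress by less than 1e-12, tight enough that
#'   zero-dissimilarity labels land on top of each other.
#' @return A list: `coords` (n x n_dims matrix, rownames = labels),
#'   `stress`, `iterations`, `stress_trace` (per-iteration stress of the
#'   winning restart), `seed`.
#' @export
mds_embed <- function(D, n_dims = 3L, seed = 1L, n_restarts = 8L,
                      max_iter = 3000L, tol = 1e-12) {
  if (inherits(D, "distance_matrix")) {
    delta <- D$d
    labels <- D$labels
  } else {
    delta <- as.matrix(D)
    labels <- rownames(delta) %||% paste0("p", seq_len(nrow(delta)))
  }
  n <- nrow(delta)
  if (n < 3L) stop_input("MDS needs at least 3 labels; got %d", n)
  stopifnot(isTRUE(all.equal(delta, t(delta))), all(delta >= 0))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- withr::with_seed(derive_seed(seed, r), {
      matrix(rnorm(n * n_dims, sd = max(delta) / 2 + 1e-12), n, n_dims)
    })
    fit <- smacof_once(delta, n_dims, init, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$X
  rownames(coords) <- labels
  colnames(coords) <- paste0("dim", seq_len(n_dims))
  list(coords = coords, stress = best$stress, iterations = best$iterations,
       stress_trace = best$trace, seed = as.integer(seed))
}

#' Project MDS coordinates to 2D by principal component analysis
#'
#' Centers the coordinates, eigen-decomposes their covariance, and
#' projects onto the top two components. Sign convention: within each
#' component the largest-magnitude loading is made positive, so the
#' projection is deterministic.
#'
#' @param coords3d numeric matrix of point coordinates (>= 2 rows).
#' @return A list: `coords2d` (n x 2, columns `PC1`, `PC2`),
#'   `explained_variance` (fractions for the kept components,
#'   non-increasing), `rotation`.
#' @export
pca_project <- function(coords3d) {
  coords3d <- as.matrix(coords3d)
  n <- nrow(coords3d)
  if (n < 2L) stop_input("PCA projection needs at least 2 points")
  pc <- prcomp(coords3d, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(2L, ncol(pc$rotation)))
  rot <- pc$rotation[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  centered <- sweep(coords3d, 2, pc$center)
  coords2d <- centered %*% rot
  colnames(coords2d) <- c("PC1", "PC2")[seq_along(keep)]
  totvar <- sum(pc$sdev^2)
  ev <- if (totvar > 0) pc$sdev[keep]^2 / totvar else rep(0, length(keep))
  list(coords2d = coords2d, explained_variance = ev, rotation = rot)
}

#' Build the Golgi atlas embedding
#'
#' The full mapping pipeline: mean pairwise colocalization to
#' dissimilarities `d = 1 - r`, 3D metric MDS (SMACOF), then a 2D PCA
#' projection whose axes are the first and second principal components of
#' the 3D configuration.
#'
#' @param measurements per-cell colocalization tibble
#'   (see [build_distance_matrix()]).
#' @param seed integer seed for the MDS restarts.
#' @param normalization passed to [build_distance_matrix()].
#' @param ... passed to [mds_embed()].
#' @return An object of class `golgi_atlas`: `distances`
#'   (`distance_matrix`), `coords3d`, `stress`, `coords2d`,
#'   `explained_variance`, `seed`.
#' @export
make_atlas <- function(measurements, seed = 1L,
                       normalization = c("none", "self-control"), ...) {
  D <- build_distance_matrix(measurements, normalization = match.arg(normalization))
  emb <- mds_embed(D, n_dims = 3L, seed = seed, ...)
  proj <- pca_project(emb$coords)
  structure(list(distances = D, coords3d = emb$coords, stress = emb$stress,
                 stress_trace = emb$stress_trace,
                 coords2d = proj$coords2d,
                 explained_variance = proj$explained_variance,
                 seed = as.integer(seed)),
            class = "golgi_atlas")
}

#' @export
print.golgi_atlas <- function(x, ...) {
  cat(sprintf("<golgi_atlas> %d enzymes, MDS stress %.3g, PC1+PC2 variance %.1f%%\n",
              nrow(x$coords2d), x$stress, 100 * sum(x$explained_variance)))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.golgi_atlas <- function(x, ...) {
  tibble(
    label = rownames(x$coords3d),
    PC1 = x$coords2d[, 1],
    PC2 = x$coords2d[, 2],
    dim1 = x$coords3d[, 1], dim2 = x$coords3d[, 2], dim3 = x$coords3d[, 3]
  )
}

#' @export
glance.golgi_atlas <- function(x, ...) {
  tibble(
    n_labels = nrow(x$coords3d),
    stress = x$stress,
    var_pc1 = x$explained_variance[1],
    var_pc2 = x$explained_variance[2],
    normalization = x$distances$normalization,
    seed = x$seed
  )
}

#' @export
autoplot.golgi_atlas <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2, label = .data$label)) +
    ggplot2::geom_point(size = 3, color = "#2166ac") +
    ggplot2::geom_text(vjust = -0.8, size = 3.4) +
    ggplot2::labs(
      title = "Golgi atlas (3D MDS of d = 1 - r, PCA-projected)",
      x = sprintf("PC1 (%.0f%%)", 100 * x$explained_variance[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * x$explained_variance[2])
    ) +
    ggplot2::theme_minimal()
}
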