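#' Pearson correlation of two intensity vectors
#'
#' The voxel-wise colocalization statistic
#' \deqn{r = \frac{\sum (a - \bar a)(b - \bar b)}{\sqrt{\sum (a - \bar a)^2 \sum (b - \bar b)^2}}}
#'
#' @param a_values,b_values numeric vectors of equal length >= 2 with
#'   nonzero variance.
#' @return The correlation, in `[-1, 1]`.
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4))
#' @export
pearson <- function(a_values, b_values) {
  if (length(a_values) != length(b_values)) stop_input("input lengths differ")
  if (length(a_values) < 2L) stop_input("need at least 2 paired values")
  if (anyNA(a_values) || anyNA(b_values)) stop_input("inputs must not contain NA")
  if (var(a_values) == 0 || var(b_values) == 0) {
    stop_input("undefined correlation: zero variance in a channel")
  }
  cor(a_values, b_values)
}

#' Costes-thresholded Pearson correlation of an image pair
#'
#' Computes the colocalization Pearson `r` over the signal voxel set
#' selected by a Costes threshold: by default the union
#' `A > t_a OR B > t_b` (`voxel_policy = "or"`), which retains mutually
#' exclusive staining so non-colocalized pairs are penalized; the
#' intersection is available as `voxel_policy = "and"`.
#'
#' @param a,b co-registered [voxel_image()] channels.
#' @param ct a [costes_thresholds()] result for this image pair.
#' @param roi optional [roi_mask()]; defaults to the whole image.
#' @param voxel_policy `"or"` (default) or `"and"`.
#' @return A list: `r`, `n_voxels`, `voxel_policy`, `thresholds` (the
#'   `costes_result`).
#' @export
thresholded_pearson <- function(a, b, ct, roi = NULL, voxel_policy = c("or", "and")) {
  stopifnot(inherits(a, "voxel_image"), inherits(b, "voxel_image"),
            inherits(ct, "costes_result"))
  voxel_policy <- match.arg(voxel_policy)
  if (!identical(dim(a$data), dim(b$data))) stop_input("channel shapes differ")
  roi <- check_roi(a, roi)
  sel <- if (voxel_policy == "or") {
    a$data > ct$t_a | b$data > ct$t_b
  } else {
    a$data > ct$t_a & b$data > ct$t_b
  }
  sel <- sel & roi$data
  n <- sum(sel)
  if (n < 2L) stop_input("signal voxel set has %d voxel(s); need >= 2", n)
  list(r = pearson(a$data[sel], b$data[sel]), n_voxels = n,
       voxel_policy = voxel_policy, thresholds = ct)
}

#' Foreground segmentation for nMDP analysis
#'
#' Thresholds each channel with Otsu or maximum-entropy (voxels strictly
#' above threshold are foreground) and returns the union of the two
#' per-channel foregrounds.
#'
#' @param a,b co-registered [voxel_image()] channels.
#' @param roi optional [roi_mask()] restricting the histograms and mask.
#' @param method `"otsu"` or `"maxentropy"`.
#' @param n_bins histogram bins for float images.
#' @return A [roi_mask()] of the foreground union, with attributes
#'   `t_a`, `t_b`, `method`.
#' @export
segment_foreground <- function(a, b, roi = NULL, method = c("otsu", "maxentropy"),
                               n_bins = 256L) {
  method <- match.arg(method)
  roi <- check_roi(a, roi)
  thr <- switch(method, otsu = otsu_threshold, maxentropy = max_entropy_threshold)
  t_a <- thr(build_histogram(a, roi, n_bins))
  t_b <- thr(build_histogram(b, roi, n_bins))
  fg <- (a$data > t_a | b$data > t_b) & roi$data
  out <- roi_mask(fg, description = sprintf("%s foreground union", method))
  attr(out, "t_a") <- t_a
  attr(out, "t_b") <- t_b
  attr(out, "method") <- method
  out
}

#' Normalized mean deviation product (nMDP) colocalization map
#'
#' Over the foreground voxel set, with channel means `abar`, `bbar` and
#' maxima `amax`, `bmax` computed on that set, each voxel gets
#' `nMDP = (A - abar) * (B - bbar) / ((amax - abar) * (bmax - bbar))`.
#' Positive values mark voxels where both channels deviate from their
#' means in the same direction (colocalized); `Icorr` is the fraction of
#' foreground voxels with positive nMDP and `Inega_corr = 1 - Icorr` the
#' non-colocalized fraction. Raw values are kept unclamped (values below
#' -1 are mathematically possible); clamping to `[-1, 1]` is applied only
#' when rendering a colormap.
#'
#' @param a,b co-registered [voxel_image()] channels.
#' @param fg foreground [roi_mask()], e.g. from [segment_foreground()].
#' @return An object of class `nmdp_result`: `field` (3D array, `NA`
#'   outside the foreground), `icorr`, `inega_corr`, `n_foreground`,
#'   `seg_method`.
#' @export
nmdp_map <- function(a, b, fg) {
  stopifnot(inherits(a, "voxel_image"), inherits(b, "voxel_image"))
  fg <- check_roi(a, fg)
  va <- a$data[fg$data]
  vb <- b$data[fg$data]
  abar <- mean(va); bbar <- mean(vb)
  amax <- max(va); bmax <- max(vb)
  if (amax == abar || bmax == bbar) {
    stop_input("nMDP undefined: a channel is constant on the foreground")
  }
  vals <- (va - abar) * (vb - bbar) / ((amax - abar) * (bmax - bbar))
  field <- array(NA_real_, dim(a$data))
  field[fg$data] <- vals
  icorr <- sum(vals > 0) / length(vals)
  structure(list(field = field, icorr = icorr, inega_corr = 1 - icorr,
                 n_foreground = length(vals),
                 seg_method = attr(fg, "method") %||% "custom"),
            class = "nmdp_result")
}

#' @export
print.nmdp_result <- function(x, ...) {
  cat(sprintf("<nmdp_result> %d foreground voxels (%s), Icorr = %.3f, Inega-corr = %.3f\n",
              x$n_foreground, x$seg_method, x$icorr, x$inega_corr))
  invisible(x)
}

#' Plot a mid-plane slice of an nMDP colormap
#'
#' Values are clamped to `[-1, 1]` for display on a diverging scale;
#' background (non-foreground) voxels are grey.
#'
#' @param x an [nmdp_map()] result.
#' @param z 1-based z-plane; defaults to the mid-plane.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nmdp_result <- function(x, z = NULL, ...) {
  d <- dim(x$field)
  z <- z %||% ((d[1] + 1L) %/% 2L)
  slab <- x$field[z, , ]
  df <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[3]))
  df$nmdp <- pmin(pmax(as.vector(t(slab)), -1), 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$nmdp)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7", high = "#b2182b",
                                  limits = c(-1, 1), na.value = "grey30") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("nMDP (z = %d), Icorr = %.3f", z, x$icorr),
                  x = "x", y = "y", fill = "nMDP") +
    ggplot2::theme_minimal()
}

# trilinear interpolation of img$data at physical (z, y, x) um points
trilinear <- function(img, pts) {
  d <- dim(img$data)
  idx <- sweep(pts, 2, img$spacing, "/")      # 0-based fractional voxel index
  lim <- d - 1L
  if (any(idx < -1e-9) || any(sweep(idx, 2, lim, "-") > 1e-9)) {
    stop_input("sample point outside the volume")
  }
  idx <- pmin(pmax(idx, 0), matrix(lim, nrow(idx), 3, byrow = TRUE))
  i0 <- pmin(floor(idx), matrix(pmax(lim - 1L, 0L), nrow(idx), 3, byrow = TRUE))
  f <- idx - i0
  i1 <- sweep(i0 + 1, 2, lim, pmin)     # upper corner clamps on size-1 axes
  at <- function(dz, dy, dx) {
    iz <- if (dz == 0) i0[, 1] else i1[, 1]
    iy <- if (dy == 0) i0[, 2] else i1[, 2]
    ix <- if (dx == 0) i0[, 3] else i1[, 3]
    img$data[cbind(iz + 1L, iy + 1L, ix + 1L)]
  }
  w <- function(fi, d1) if (d1 == 1) fi else 1 - fi
  out <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    out <- out + at(dz, dy, dx) * w(f[, 1], dz) * w(f[, 2], dy) * w(f[, 3], dx)
  }
  out
}

#' Multi-channel fluorescence intensity line profile
#'
#' Samples each channel by trilinear interpolation at `n_samples`
#' equispaced points along the segment from `p0` to `p1` (physical um
#' coordinates, `(z, y, x)`, voxel centers at `index * spacing`), then
#' normalizes each channel to its own maximum along the profile — the
#' standard presentation for comparing peak positions of cis/medial/trans
#' markers across a Golgi stack.
#'
#' @param img a [multi_channel_image()] (or single [voxel_image()]).
#' @param p0,p1 segment endpoints, um `(z, y, x)`.
#' @param n_samples number of sample points (>= 2).
#' @return A tibble with columns `position_um`, `channel`, `intensity`
#'   (normalized), `raw_intensity`.
#' @export
line_profile <- function(img, p0, p1, n_samples = 100L) {
  if (inherits(img, "voxel_image")) img <- multi_channel_image(list(img), "")
  stopifnot(inherits(img, "multi_channel_image"), n_samples >= 2L)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 3L, length(p1) == 3L)
  if (all(p0 == p1)) stop_input("profile endpoints coincide")
  tfrac <- seq(0, 1, length.out = n_samples)
  pts <- outer(tfrac, p1 - p0) + matrix(p0, n_samples, 3, byrow = TRUE)
  pos <- tfrac * sqrt(sum((p1 - p0)^2))
  purrr::imap_dfr(img$channels, function(ch, i) {
    raw <- trilinear(ch, pts)
    mx <- max(raw)
    lab <- if (nzchar(ch$channel_label)) ch$channel_label else paste0("channel_", i)
    tibble(position_um = pos, channel = lab,
           intensity = if (mx > 0) raw / mx else raw,
           raw_intensity = raw)
  })
}

#' Full colocalization analysis of one two-channel scene
#'
#' Composes the measurement pipeline on the whole-image ROI (or a supplied
#' mask): Costes bivariate thresholding followed by thresholded Pearson
#' correlation, and Otsu/max-entropy segmentation followed by the nMDP
#' colormap with Icorr. Full provenance (thresholds, regression, policies)
#' is returned for the results table.
#'
#' @param scene a [multi_channel_image()] with two channels, or a
#'   `synthetic_scene` from [render_cell()]/[render_panel()].
#' @param roi optional [roi_mask()].
#' @param seg_method `"otsu"` (default) or `"maxentropy"` for the nMDP
#'   foreground.
#' @param voxel_policy Pearson signal-set policy, `"or"` (default) or `"and"`.
#' @param below_set Costes below-set logic, `"and"` (default) or `"or"`.
#' @param n_bins histogram bins for float images.
#' @return A list with `measurement` (one-row tibble) and `nmdp`
#'   (an `nmdp_result`).
#' @export
colocalize_pair <- function(scene, roi = NULL, seg_method = c("otsu", "maxentropy"),
                            voxel_policy = c("or", "and"),
                            below_set = c("and", "or"), n_bins = 256L) {
  seg_method <- match.arg(seg_method)
  voxel_policy <- match.arg(voxel_policy)
  below_set <- match.arg(below_set)
  truth <- NULL
  if (inherits(scene, "synthetic_scene")) {
    truth <- scene
    scene <- scene$image
  }
  stopifnot(inherits(scene, "multi_channel_image"))
  if (length(scene$channels) != 2L) stop_input("colocalize_pair needs exactly 2 channels")
  a <- scene$channels[[1]]; b <- scene$channels[[2]]
  ct <- costes_thresholds(a, b, roi, below_set = below_set)
  tp <- thresholded_pearson(a, b, ct, roi, voxel_policy = voxel_policy)
  fg <- segment_foreground(a, b, roi, method = seg_method, n_bins = n_bins)
  nm <- nmdp_map(a, b, fg)
  label_a <- truth$label_a %||% (if (nzchar(a$channel_label)) a$channel_label else "A")
  label_b <- truth$label_b %||% (if (nzchar(b$channel_label)) b$channel_label else "B")
  measurement <- tibble(
    cell_id = truth$cell_id %||% scene$cell_id,
    label_a = label_a, label_b = label_b,
    r = tp$r, n_voxels = tp$n_voxels,
    t_a = ct$t_a, t_b = ct$t_b, slope = ct$slope, intercept = ct$intercept,
    costes_converged = ct$converged, below_set = below_set,
    voxel_policy = voxel_policy,
    seg_method = seg_method, icorr = nm$icorr, inega_corr = nm$inega_corr,
    n_foreground = nm$n_foreground,
    pair_offset = truth$pair_offset %||% NA_real_,
    seed = truth$seed %||% NA_integer_
  )
  list(measurement = measurement, nmdp = nm)
}

#' Batch colocalization over a list of scenes
#'
#' @param scenes list of scenes ([render_panel()] output or
#'   [multi_channel_image()] objects).
#' @param ... passed to [colocalize_pair()].
#' @return A tibble with one measurement row per scene.
#' @export
colocalize_scenes <- function(scenes, ...) {
  purrr::map_dfr(scenes, function(sc) colocalize_pair(sc, ...)$measurement)
}
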