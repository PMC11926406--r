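#' Intensity histogram of an image region
#'
#' Integer-valued images get one bin per integer level spanning
#' `[min, max]` (so thresholds are exact intensity levels); float images
#' get `n_bins` equal-width bins with bin-center values. A constant image
#' yields a single-bin histogram flagged degenerate.
#'
#' @param img a [voxel_image()].
#' @param roi optional [roi_mask()]; defaults to the whole image.
#' @param n_bins bin count for float-valued images (default 256).
#' @return An object of class `intensity_histogram` with fields
#'   `bin_edges`, `counts`, `values` (candidate threshold per bin),
#'   `degenerate`, `integer_levels`.
#' @export
build_histogram <- function(img, roi = NULL, n_bins = 256L) {
  stopifnot(inherits(img, "voxel_image"), n_bins >= 1L)
  roi <- check_roi(img, roi)
  vals <- img$data[roi$data]
  lo <- min(vals); hi <- max(vals)
  if (lo == hi) {
    return(structure(list(bin_edges = c(lo - 0.5, lo + 0.5), counts = length(vals),
                          values = lo, degenerate = TRUE,
                          integer_levels = all(vals == round(vals))),
                     class = "intensity_histogram"))
  }
  if (all(vals == round(vals))) {
    values <- seq(lo, hi)
    counts <- tabulate(vals - lo + 1, nbins = hi - lo + 1)
    edges <- seq(lo - 0.5, hi + 0.5)
    integer_levels <- TRUE
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1)
    bin <- findInterval(vals, edges, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(bin, nbins = n_bins)
    values <- (edges[-1] + edges[-length(edges)]) / 2
    integer_levels <- FALSE
  }
  structure(list(bin_edges = edges, counts = counts, values = values,
                 degenerate = FALSE, integer_levels = integer_levels),
            class = "intensity_histogram")
}

check_thresholdable <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (isTRUE(h$degenerate) || sum(h$counts > 0) < 2L) {
    stop_input("histogram is degenerate (fewer than two occupied levels)")
  }
}

#' Otsu threshold
#'
#' Returns the bin value `t` maximizing the between-class variance
#' `w0(t) * w1(t) * (mu0(t) - mu1(t))^2`, where class 0 collects bins with
#' value `<= t` (background) and class 1 the rest (foreground: intensity
#' strictly above the threshold). Ties break to the lowest optimal `t`.
#'
#' @param h an [build_histogram()] result with >= 2 occupied bins.
#' @return The threshold intensity (a bin value).
#' @export
otsu_threshold <- function(h) {
  check_thresholdable(h)
  p <- as.numeric(h$counts)
  v <- h$values
  total <- sum(p)
  grand <- sum(p * v)
  c0 <- cumsum(p)
  s0 <- cumsum(p * v)
  k <- length(p)
  i <- seq_len(k - 1L)          # thresholding at the last bin leaves no foreground
  w0 <- c0[i] / total
  w1 <- 1 - w0
  mu0 <- ifelse(c0[i] > 0, s0[i] / c0[i], 0)
  mu1 <- ifelse(total - c0[i] > 0, (grand - s0[i]) / (total - c0[i]), 0)
  crit <- w0 * w1 * (mu0 - mu1)^2
  crit[w0 == 0 | w1 == 0] <- -Inf
  v[i][which.max(crit)]
}

#' Maximum-entropy (Kapur) threshold
#'
#' Returns the bin value `t` maximizing the sum of Shannon entropies of the
#' renormalized background (`value <= t`) and foreground (`value > t`)
#' class histograms, with the `0 * log 0 = 0` convention. Ties break to the
#' lowest optimal `t`.
#'
#' @inheritParams otsu_threshold
#' @return The threshold intensity (a bin value).
#' @export
max_entropy_threshold <- function(h) {
  check_thresholdable(h)
  p <- as.numeric(h$counts) / sum(h$counts)
  v <- h$values
  plogp <- ifelse(p > 0, -p * log(p), 0)
  P0 <- cumsum(p)
  E0 <- cumsum(plogp)
  Etot <- E0[length(E0)]
  k <- length(p)
  i <- seq_len(k - 1L)
  valid <- P0[i] > 0 & P0[i] < 1
  H0 <- ifelse(valid, log(P0[i]) + E0[i] / P0[i], -Inf)
  H1 <- ifelse(valid, log(1 - P0[i]) + (Etot - E0[i]) / (1 - P0[i]), -Inf)
  crit <- H0 + H1
  v[i][which.max(crit)]
}

#' Costes automatic bivariate threshold
#'
#' Implements the regression-guided automatic threshold for two-channel
#' colocalization. A total-least-squares (orthogonal, principal-axis) line
#' `B = slope * A + intercept` is fitted to the ROI voxel scatter; then
#' candidate thresholds `t_a` are scanned from `max(A)` downward over the
#' occupied intensity levels of channel A with `t_b = slope * t_a +
#' intercept`, and at each step the Pearson correlation of the
#' below-threshold voxel set (`A <= t_a` and `B <= t_b` for the default
#' `below_set = "and"`) is evaluated. The scan stops at the largest `t_a`
#' whose below-set correlation is `<= 0` (requiring at least two distinct
#' values per channel in the set); voxels above threshold are the signal.
#' If no crossing exists, thresholds fall to the channel-A minimum (with
#' `t_b` still on the regression line) and `converged` is `FALSE`.
#'
#' @param a,b co-registered [voxel_image()] channels.
#' @param roi optional [roi_mask()]; defaults to the whole image.
#' @param below_set `"and"` (both channels below; default) or `"or"`,
#'   exposed for sensitivity checks.
#' @return An object of class `costes_result`: `t_a`, `t_b`, `slope`,
#'   `intercept`, `r_below_at_stop`, `converged`, plus the full `scan`
#'   tibble of candidate levels and their below-set correlations.
#' @export
costes_thresholds <- function(a, b, roi = NULL, below_set = c("and", "or")) {
  stopifnot(inherits(a, "voxel_image"), inherits(b, "voxel_image"))
  below_set <- match.arg(below_set)
  if (!identical(dim(a$data), dim(b$data))) stop_input("channel shapes differ")
  roi <- check_roi(a, roi)
  va <- a$data[roi$data]
  vb <- b$data[roi$data]
  n <- length(va)
  if (n < 16L) stop_input("Costes needs >= 16 ROI voxels; got %d", n)
  if (var(va) == 0 || var(vb) == 0) stop_input("Costes needs variance in both channels")

  # orthogonal regression: principal axis of the 2x2 covariance
  cv <- stats::cov(cbind(va, vb))
  ev <- eigen(cv, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  if (v1[1] < 0) v1 <- -v1
  slope <- v1[2] / v1[1]
  if (!is.finite(slope) || slope <= 0) {
    stop_input("negative-slope: Costes undefined (anti-correlated channels)")
  }
  intercept <- mean(vb) - slope * mean(va)

  # one-sweep scan over occupied levels of channel A (descending); a voxel
  # joins the below set once t_a reaches its entry level
  # e = max(A, (B - intercept)/slope) ("and") or the min ("or")
  sc <- cpp_costes_scan(va, vb, slope, intercept, below_set == "and")
  cand <- sc$t_a
  r_below <- sc$r_below
  hit <- which(!is.na(r_below) & r_below <= 0)
  scan <- tibble(t_a = cand, n_below = as.integer(sc$n_below), r_below = r_below)
  if (length(hit) > 0) {
    i <- hit[1]
    t_a <- cand[i]
    res <- list(t_a = t_a, t_b = slope * t_a + intercept, slope = slope,
                intercept = intercept, r_below_at_stop = r_below[i],
                converged = TRUE)
  } else {
    t_a <- min(va)
    res <- list(t_a = t_a, t_b = slope * t_a + intercept, slope = slope,
                intercept = intercept, r_below_at_stop = NA_real_,
                converged = FALSE)
  }
  res$below_set <- below_set
  res$n_roi <- n
  res$scan <- scan
  structure(res, class = "costes_result")
}

#' @export
print.costes_result <- function(x, ...) {
  cat(sprintf(
    "<costes_result> t_a = %.4g, t_b = %.4g (B = %.4g A + %.4g), %s (r_below = %.4g)\n",
    x$t_a, x$t_b, x$slope, x$intercept,
    if (x$converged) "converged" else "no zero-crossing",
    if (is.na(x$r_below_at_stop)) NA else x$r_below_at_stop))
  invisible(x)
}
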