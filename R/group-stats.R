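#' Per-group mean and SEM of per-cell colocalization values
#'
#' The figure-legend summary: group mean, sample SD (n - 1 denominator)
#' and standard error of the mean. A single-observation group gets
#' `NA` SD/SEM and is flagged.
#'
#' @param data data frame of per-cell values.
#' @param value,group columns (tidy-eval) holding the per-cell statistic
#'   and the group label.
#' @return A tibble: `group`, `n_cells`, `mean`, `sd`, `sem`,
#'   `sem_defined`.
#' @examples
#' summarize_groups(data.frame(g = c("a", "a"), r = c(0.5, 0.7)), r, g)
#' @export
summarize_groups <- function(data, value, group) {
  stopifnot(is.data.frame(data))
  out <- data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean = mean({{ value }}),
      sd = sd({{ value }}),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n_cells),
                  sem_defined = .data$n_cells >= 2L)
  if (any(out$n_cells < 1L)) stop_input("empty group")
  out
}

# pooled-variance many-to-one t statistics and the contrast correlation
dunnett_stats <- function(values, groups, control) {
  tab <- split(values, groups)
  if (!control %in% names(tab)) stop_input("control group '%s' not found", control)
  ns <- lengths(tab)
  if (any(ns < 2L)) stop_input("every group needs n >= 2 for Dunnett's test")
  k <- length(tab)
  if (k < 2L) stop_input("need at least one non-control group")
  means <- vapply(tab, mean, numeric(1))
  ss <- vapply(tab, function(v) sum((v - mean(v))^2), numeric(1))
  df <- sum(ns) - k
  s2 <- sum(ss) / df
  others <- setdiff(names(tab), control)
  n0 <- ns[[control]]
  t_stat <- (means[others] - means[[control]]) /
    sqrt(s2 * (1 / ns[others] + 1 / n0))
  lam <- sqrt(ns[others] / (ns[others] + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  list(t = t_stat, df = df, corr = corr, others = others,
       estimate = means[others] - means[[control]])
}

#' Dunnett's many-to-one comparisons against a control group
#'
#' Classic equal-variance Dunnett test: each treatment group is compared
#' to the control with pooled within-group variance, and the two-sided
#' family-wise adjusted p-value is obtained from the joint multivariate t
#' distribution of the contrasts (numerical integration via
#' \pkg{mvtnorm}, absolute accuracy about 5e-4, so adjusted p-values are
#' accurate to roughly +/- 0.002). Adjusted p-values are never reported
#' below the corresponding unadjusted two-sample p.
#'
#' @param data data frame of per-cell values.
#' @param value,group columns (tidy-eval) with the statistic and group label.
#' @param control control group label.
#' @param seed integer seed for the deterministic quasi-Monte-Carlo
#'   integration lattice.
#' @return A tibble with one row per non-control group: `comparison`,
#'   `estimate`, `statistic`, `df`, `p_unadjusted`, `p_adjusted`, `stars`,
#'   `method`.
#' @export
dunnett_vs_control <- function(data, value, group, control, seed = 1L) {
  stopifnot(is.data.frame(data))
  values <- dplyr::pull(data, {{ value }})
  groups <- as.character(dplyr::pull(data, {{ group }}))
  st <- dunnett_stats(values, groups, control)
  p_unadj <- 2 * pt(abs(st$t), st$df, lower.tail = FALSE)
  p_adj <- withr::with_seed(as.integer(seed), {
    vapply(abs(st$t), function(tt) {
      1 - mvtnorm::pmvt(lower = rep(-tt, length(st$t)),
                        upper = rep(tt, length(st$t)),
                        df = as.integer(st$df), corr = st$corr,
                        algorithm = mvtnorm::GenzBretz(abseps = 5e-4))[1]
    }, numeric(1))
  })
  p_adj <- pmin(pmax(p_adj, p_unadj), 1)   # family-wise p dominates marginal p
  tibble(
    comparison = paste(st$others, "vs", control),
    estimate = unname(st$estimate),
    statistic = unname(st$t),
    df = st$df,
    p_unadjusted = unname(p_unadj),
    p_adjusted = unname(p_adj),
    stars = signif_stars(unname(p_adj)),
    method = "dunnett"
  )
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' @param x,y numeric vectors, each with n >= 2.
#' @return A one-row tibble: `comparison`, `estimate`, `statistic`, `df`,
#'   `p_adjusted` (the unadjusted two-sided p — a single comparison has no
#'   family), `stars`, `method`.
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop_input("both samples need n >= 2")
  fit <- stats::t.test(x, y, var.equal = TRUE)
  tibble(
    comparison = "x vs y",
    estimate = unname(fit$estimate[1] - fit$estimate[2]),
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_adjusted = fit$p.value,
    stars = signif_stars(fit$p.value),
    method = "t_test"
  )
}
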