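# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive loops / direct formulas so
# they share no code path with the functions they check.

# two-pass Pearson correlation straight from the definition
oracle_pearson <- function(a, b) {
  am <- sum(a) / length(a)
  bm <- sum(b) / length(b)
  num <- sum((a - am) * (b - bm))
  num / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# exhaustive Otsu: evaluate between-class variance at every candidate level
oracle_otsu <- function(counts, values) {
  k <- length(counts)
  best <- -Inf; best_t <- NA
  total <- sum(counts)
  for (i in seq_len(k - 1)) {
    w0 <- 0; s0 <- 0
    for (j in 1:i) { w0 <- w0 + counts[j]; s0 <- s0 + counts[j] * values[j] }
    w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    s1 <- sum(counts * values) - s0
    crit <- (w0 / total) * (w1 / total) * (s0 / w0 - s1 / w1)^2
    if (crit > best) { best <- crit; best_t <- values[i] }
  }
  best_t
}

# exhaustive Kapur maximum-entropy threshold
oracle_max_entropy <- function(counts, values) {
  p <- counts / sum(counts)
  k <- length(p)
  best <- -Inf; best_t <- NA
  for (i in seq_len(k - 1)) {
    p0 <- sum(p[1:i]); p1 <- 1 - p0
    if (p0 <= 0 || p1 <= 0) next
    h0 <- 0
    for (j in 1:i) if (p[j] > 0) h0 <- h0 - (p[j] / p0) * log(p[j] / p0)
    h1 <- 0
    for (j in (i + 1):k) if (p[j] > 0) h1 <- h1 - (p[j] / p1) * log(p[j] / p1)
    crit <- h0 + h1
    if (crit > best) { best <- crit; best_t <- values[i] }
  }
  best_t
}

# dense eigen-decomposition PCA oracle with the same sign convention
oracle_pca_2d <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  rot <- ev$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  list(coords2d = Xc %*% rot,
       explained_variance = ev$values[1:2] / sum(ev$values))
}

# pooled-variance two-sample t-test from the textbook formula
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t_stat, df = n1 + n2 - 2,
       p = 2 * pt(abs(t_stat), n1 + n2 - 2, lower.tail = FALSE))
}
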