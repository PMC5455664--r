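# Independent brute-force oracles used to check the package's numerics.
# These deliberately avoid the code paths (and where possible the library
# calls) they are checking.

pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sx <- sqrt(sum((x - mx)^2)); sy <- sqrt(sum((y - my)^2))
  sxy / (sx * sy)
}

euclidean_oracle <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  D
}

# Naive O(n^3) UPGMA: clusters as index sets; inter-cluster distance is the
# plain average of all cross-pair leaf distances. Returns sorted merge
# heights (the merge-order multiset, which is linkage-order invariant).
upgma_heights_oracle <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Textbook one-way fixed-effects sum-of-squares decomposition.
anova_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_b <- 0; ss_w <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - grand)^2
    ss_w <- ss_w + sum((v - mean(v))^2)
  }
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# Quartile by linear interpolation of order statistics (the type-7
# convention), written out directly.
quantile_oracle <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

box_oracle <- function(v) {
  q25 <- quantile_oracle(v, 0.25); q75 <- quantile_oracle(v, 0.75)
  iqr <- q75 - q25
  inliers <- v[v >= q25 - 1.5 * iqr & v <= q75 + 1.5 * iqr]
  list(median = quantile_oracle(v, 0.5), q25 = q25, q75 = q75,
       whisker_lo = min(inliers), whisker_hi = max(inliers),
       n_outliers = sum(v < q25 - 1.5 * iqr | v > q75 + 1.5 * iqr))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
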