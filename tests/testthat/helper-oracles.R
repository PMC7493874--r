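# Independent brute-force oracles used to pin the package's implementations.

# Optimal two-cluster 1D K-means: the optimum is a contiguous split of the
# sorted values, so exhaustive search over the n-1 split points is exact.
oracle_two_means <- function(values) {
  v <- sort(values)
  n <- length(v)
  ss <- function(x) if (length(x) <= 1) 0 else sum((x - mean(x))^2)
  best <- list(wcss = Inf)
  for (i in seq_len(n - 1)) {
    lo <- v[seq_len(i)]
    hi <- v[(i + 1):n]
    w <- ss(lo) + ss(hi)
    if (w < best$wcss) {
      best <- list(wcss = w, centroid_lo = mean(lo), centroid_hi = mean(hi),
                   threshold = (mean(lo) + mean(hi)) / 2)
    }
  }
  best
}

# Enrichment factor by sort, slice, count.
oracle_ef <- function(scores, is_active, p) {
  ord <- order(-scores)
  n <- length(scores)
  window <- floor(p * n / 100)
  hits <- sum(is_active[ord][seq_len(window)])
  list(window = window, hits = hits,
       percent = 100 * hits / min(window, sum(is_active)))
}

# AUC over all active/inactive pairs, ties counting one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Majority vote by explicit counting.
oracle_majority <- function(v) as.integer(sum(v) > length(v) / 2)

# Small planted-signal feature set for classifier tests: class-1 rows carry
# +1 on a fixed block of columns, everything else is random +/-1.
planted_data <- function(n, n_bits, signal_cols = 1:6, seed = 1) {
  set.seed(seed)
  X <- matrix(sample(c(-1, 1), n * n_bits, replace = TRUE), n)
  y <- rep(c(1, 0), length.out = n)
  X[y == 1, signal_cols] <- 1
  list(x = X, y = y)
}

# Exact double-precision reference forward pass for the degenerate network
# with 1x1 kernels and single-channel conv layers (each conv is then a
# scalar affine map), against which the engine's forward is pinned.
reference_forward_1x1 <- function(w, X, k_rows) {
  sapply(seq_len(nrow(X)), function(s) {
    A <- matrix(X[s, ], nrow = k_rows)
    for (li in 1:4) {
      A <- pmax(w[[2 * li - 1]][1, 1] * A + w[[2 * li]][1, 1], 0)
      H <- nrow(A)
      ph <- if (H >= 2) 2 else 1
      Ap <- matrix(0, H %/% ph, ncol(A) %/% 2)
      for (i in seq_len(nrow(Ap))) {
        for (j in seq_len(ncol(Ap))) {
          Ap[i, j] <- max(A[((i - 1) * ph + 1):(i * ph), (2 * j - 1):(2 * j)])
        }
      }
      A <- Ap
    }
    h <- as.vector(A)
    n_dense <- (length(w) - 8 - 2) / 2
    for (dj in seq_len(n_dense)) {
      h <- pmax(w[[8 + 2 * dj - 1]] %*% h + as.vector(w[[8 + 2 * dj]]), 0)
    }
    z <- as.vector(w[[length(w) - 1]] %*% h) + w[[length(w)]][1, 1]
    1 / (1 + exp(-z))
  })
}
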