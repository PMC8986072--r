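# Independent brute-force reference implementations used as oracles.
# These are deliberately written as plain loops over the defining formulas,
# not as mirrors of the package code.

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m * p_(j) / j, clipped.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Holm-Sidak step-down: adj_(i) = max_{j <= i} 1 - (1 - p_(j))^(m - j + 1).
brute_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, 1 - (1 - ps[i])^(m - i + 1))
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by exhaustive enumeration of overlap sizes.
brute_hyper_tail <- function(k, K, N, n) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Cophenetic distances recomputed from an hclust merge record.
coph_from_merge <- function(hc) {
  n <- length(hc$labels)
  D <- matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  clusters <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    get <- function(x) if (x < 0) -x else clusters[[x]]
    a <- get(hc$merge[s, 1])
    b <- get(hc$merge[s, 2])
    for (i in a) for (j in b) D[i, j] <- D[j, i] <- hc$height[s]
    clusters[[s]] <- c(a, b)
  }
  D
}

# Pearson r from the raw textbook sum formula.
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
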