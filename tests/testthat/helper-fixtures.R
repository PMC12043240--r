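# Shared fixtures and independent oracles for the test suite.
# Oracles here deliberately use direct probability sums, not the package's
# entropy-combination code paths.

# Brute-force MI oracle: double sum over the joint table
mi_oracle <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) tot <- tot + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  tot
}

# Random code vectors with every symbol guaranteed present
rand_codes <- function(n, k, prob = NULL) {
  v <- c(seq_len(k) - 1L, sample(0:(k - 1), n - k, TRUE, prob = prob))
  structure(sample(v), n_bins = k)
}

# Enumerate-and-replicate: exact empirical distribution from a probability
# table over tuples (rows of `tuples`, integer weights `w`)
exact_data <- function(tuples, w) {
  idx <- rep(seq_len(nrow(tuples)), times = w)
  tuples[idx, , drop = FALSE]
}

# Binary symmetric channel: Y = X flipped with probability pflip
bsc_sample <- function(n, pflip) {
  x <- sample(0:1, n, TRUE)
  y <- ifelse(stats::runif(n) < pflip, 1L - x, x)
  list(x = structure(x, n_bins = 2L), y = structure(as.integer(y), n_bins = 2L))
}

bsc_true_mi <- function(pflip) {
  h2 <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  1 - h2(pflip)
}

# Binary-input channel with an 8-bin discretized Gaussian response:
# X in {0,1}, Z ~ N(+-mu, 1), R = fixed-edge binning of Z. The exact MI is
# available in closed form from normal CDF differences, and the response
# alphabet is large enough that the limited-sampling bias dominates at
# n = 32..128 (the regime bias corrections are for).
gauss_channel <- local({
  edges <- c(-Inf, seq(-2, 2, length.out = 7), Inf)
  mu <- 0.6
  list(
    true_mi = {
      p_joint <- sapply(c(-mu, mu), function(m) diff(stats::pnorm(edges, mean = m))) / 2
      p_r <- rowSums(p_joint)
      sum(p_joint * log2(p_joint / (p_r %o% c(0.5, 0.5))))
    },
    sample = function(n) {
      x <- sample(0:1, n, TRUE)
      z <- stats::rnorm(n, mean = ifelse(x == 1, mu, -mu))
      list(x = structure(x, n_bins = 2L),
           r = structure(as.integer(findInterval(z, edges[2:8])), n_bins = 8L))
    })
})

# Uniform-random trial data for (s, r1, r2) with given alphabet sizes
rand_triple <- function(n, ks = 2L, k1 = 2L, k2 = 2L) {
  list(s = rand_codes(n, ks), r1 = rand_codes(n, k1), r2 = rand_codes(n, k2))
}

# XOR system on exact uniform data (each input combination `reps` times)
xor_system <- function(reps = 4L) {
  g <- expand.grid(x1 = 0:1, x2 = 0:1)
  g <- g[rep(seq_len(4), each = reps), ]
  list(x1 = structure(g$x1, n_bins = 2L),
       x2 = structure(g$x2, n_bins = 2L),
       y = structure(bitwXor(g$x1, g$x2), n_bins = 2L))
}
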