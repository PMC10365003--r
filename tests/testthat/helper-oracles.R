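# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the package's own code paths.

# Average ranks computed from first principles (positions in the sorted
# order, averaged within tie groups).
oracle_rank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  pos <- seq_along(x)[order(ord)]  # position of each x in sorted order
  for (v in unique(x)) {
    i <- which(x == v)
    r[i] <- mean(pos[i])
  }
  r
}

# Pearson correlation via raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Spearman via average-rank Pearson.
oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

# Noiseless mono-exponential series.
make_series <- function(K, T2, tes = default_echo_train(), floor = 0) {
  echo_series(tes, K * exp(-tes / T2) + floor)
}

# Uniform one-region phantom spec.
uniform_phantom <- function(T2, K = 1000, shape = c(10L, 10L), sigma = 0,
                            tes = default_echo_train()) {
  mask <- rect_mask(shape, 3:8, 3:8)
  list(spec = phantom_spec(shape,
                           list(tissue = list(mask = mask,
                                              params = decay_params(K, T2, sigma = sigma))),
                           tes),
       mask = mask)
}
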