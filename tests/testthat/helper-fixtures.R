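# small configs shared across test files; all sizes chosen for test speed,
# scientific defaults live in sim_config() itself.
small_config <- function(n = 1500L, ...) sim_config(n_subjects = n, ...)

# brute-force chi-squared oracle: explicit observed/expected double loop,
# independent of the vectorized implementation it checks.
chisq_oracle <- function(m) {
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- sum(m[i, ]) * sum(m[, j]) / n
    stat <- stat + (m[i, j] - e)^2 / e
  }
  list(statistic = stat, df = (nrow(m) - 1) * (ncol(m) - 1))
}

random_table <- function(max_dim = 6L) {
  r <- sample(2:max_dim, 1); cc <- sample(2:max_dim, 1)
  m <- matrix(rpois(r * cc, lambda = sample(1:30, 1)), r, cc)
  if (sum(m) == 0) m[1, 1] <- 1
  m
}
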