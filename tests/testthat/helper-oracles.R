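# independent oracles, kept free of the package's fitting code paths

# exhaustive (S0, T2) grid search for the mono-exponential model:
# for fixed T2 the optimal S0 is linear least squares, so the search is
# one-dimensional over the T2 grid
grid_search_t2 <- function(s, t, grid = seq(1, 500, by = 0.1)) {
  E <- exp(-outer(t, 1 / grid))          # n_echo x n_grid
  denom <- colSums(E^2)
  num <- drop(s %*% E)
  sse <- sum(s^2) - num^2 / denom
  i <- which.min(sse)
  list(t2 = grid[i], s0 = num[i] / denom[i], sse = sse[i])
}

# vectorised multi-voxel version (rows of S are voxels)
grid_search_t2_many <- function(S, t, grid = seq(1, 500, by = 0.1)) {
  E <- exp(-outer(t, 1 / grid))
  denom <- colSums(E^2)
  num <- S %*% E                          # n_vox x n_grid
  sse <- rowSums(S^2) - sweep(num^2, 2, denom, "/")
  grid[max.col(-sse, ties.method = "first")]
}

# full-enumeration Mann-Whitney two-sided p, written independently
enumerate_mw_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  cols <- utils::combn(n, na)
  us <- apply(cols, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# two-way ANOVA mean squares by explicit sums, for the ICC oracle
anova_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

# coarse direct likelihood maximisation over a 5-D parameter grid for the
# two-component Gaussian mixture
gmm2_grid_loglik <- function(x, mu1s, mu2s, sg1s, sg2s, lams) {
  best <- list(ll = -Inf)
  for (m1 in mu1s) for (m2 in mu2s) for (s1 in sg1s) for (s2 in sg2s)
    for (lm in lams) {
      ll <- sum(log(lm * stats::dnorm(x, m1, s1) +
                      (1 - lm) * stats::dnorm(x, m2, s2)))
      if (ll > best$ll) best <- list(ll = ll, mu = c(m1, m2),
                                     sigma = c(s1, s2), lambda = lm)
    }
  best
}
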