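# Shared fixtures: small cohorts and matrices built in code.

# three well-separated planted clusters over the panel, equal proportions
three_cluster_config <- function(seed, n_tumor = 300L, noise_sd = 1,
                                 shift = 2) {
  cs <- default_cluster_spec(shift = shift)[c("A", "D", "F")]
  for (i in seq_along(cs)) cs[[i]]$proportion <- 1 / 3
  cohort_config(n_tumor = n_tumor, n_normal = 0L, n_background_genes = 0L,
                cluster_spec = cs, noise_sd = noise_sd, seed = seed)
}

# tiny deterministic genes x samples matrix
toy_matrix <- function(nr = 4, nc = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, 8, 1), nr, nc,
              dimnames = list(paste0("G", seq_len(nr)),
                              paste0("S", seq_len(nc))))
  m
}

# enumeration oracle: exact two-sided Wilcoxon rank-sum p over all
# C(n+m, n) assignments of ranks to x
enumerate_ranksum_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  w_all <- colSums(matrix(seq_len(n + m)[combos], nrow = n)) -
    n * (n + 1) / 2
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# direct multivariate-normal log-density oracle
dmvnorm_oracle <- function(x, mean, sigma) {
  d <- length(mean)
  -0.5 * t(x - mean) %*% solve(sigma) %*% (x - mean) -
    0.5 * log(det(sigma)) - 0.5 * d * log(2 * pi)
}
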