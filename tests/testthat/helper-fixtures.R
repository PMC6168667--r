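# Shared fixtures: reduced-size simulation configs for unit tests (the full
# 170-trial design is exercised in the acceptance suite), a hand-built ICA
# container for testing the component-scoring criteria in isolation, and
# independent brute-force oracles for the statistics.

tiny_sim <- function(..., seed = 1L) {
  simulate_session(
    simulation_config(n_per_condition_per_block = 4L, n_edge_p = 2L,
                      iti_s = c(2.2, 2.5), ...),
    subject_seed = seed)
}

tiny_noiseless <- function(..., seed = 1L) {
  simulate_session(
    noiseless_config(n_per_condition_per_block = 4L, n_edge_p = 2L,
                     iti_s = c(2.2, 2.5), ...),
    subject_seed = seed)
}

# Minimal ppi_ica object from given activations (comps x samples x epochs
# array) and mixing matrix, for unit tests of the scoring criteria.
fake_ica <- function(act, mixing = NULL, rate = 512,
                     window_ms = c(-1000, 1000)) {
  d <- dim(act)
  if (is.null(mixing)) mixing <- diag(d[1])
  structure(list(
    activations = matrix(act, nrow = d[1]),
    mixing = mixing,
    unmixing = tryCatch(solve(mixing), error = function(e) NULL),
    n_samples = d[2], n_epochs = d[3],
    rate = rate, window_ms = window_ms
  ), class = "ppi_ica")
}

# Amari separation index between estimated unmixing and true mixing; 0 for a
# scaled permutation.
amari_index <- function(unmixing, true_mixing) {
  P <- abs(unmixing %*% true_mixing)
  n <- nrow(P)
  rowterm <- sum(rowSums(P / apply(P, 1, max)) - 1)
  colterm <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rowterm + colterm) / (2 * n * (n - 1))
}

# Friedman chi-square from first principles (within-row ranks).
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  12 / (n * k * (k + 1)) * sum((colSums(r) - n * (k + 1) / 2)^2)
}

# Exact two-sided paired Wilcoxon signed-rank p by enumerating all 2^n sign
# patterns of the rank sum (no zeros/ties assumed).
wilcoxon_exact_oracle <- function(x, y) {
  d <- x - y
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% rk)
  p_le <- mean(v_null <= v_obs)
  p_ge <- mean(v_null >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Kendall tau-b by O(n^2) pair counting with tie corrections.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# leave-one-out mean + 3 SD outlier rule from first principles.
outliers_oracle <- function(v) {
  sapply(seq_along(v), function(i) {
    v[i] > mean(v[-i]) + 3 * stats::sd(v[-i])
  })
}

expect_all_close <- function(a, b, tol) {
  expect_true(all(abs(a - b) < tol),
              info = paste("max deviation", max(abs(a - b))))
}
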