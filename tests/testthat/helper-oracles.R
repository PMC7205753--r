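# Independent oracles used across test files.

# Naive log-rank risk-set enumeration: loops over distinct event times and
# recomputes every count from scratch. Deliberately independent of the
# package's cumulative-sum implementation.
naive_logrank_uv <- function(time, event, group) {
  group <- as.logical(group)
  u <- 0; v <- 0
  for (s in sort(unique(time[event == 1]))) {
    at_risk <- time >= s
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == s & event == 1)
    d1 <- sum(time == s & event == 1 & group)
    u <- u + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  list(u = u, v = v)
}

# Equicorrelated (rho = 1/2) multivariate normal draws via the shared-
# control representation Z_i = (W_i - W_0) / sqrt(2), W iid standard normal.
requicorr_half <- function(n, k) {
  w0 <- rnorm(n)
  sapply(seq_len(k), function(i) (rnorm(n) - w0) / sqrt(2))
}

# random small survival dataset for oracle comparisons
random_survival_data <- function(n_max = 20) {
  n <- sample(4:n_max, 1)
  # integer-ish times force ties through the hypergeometric correction
  time <- sample(1:8, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
  event <- rbinom(n, 1, 0.7)
  group <- c(TRUE, FALSE, rbinom(n - 2, 1, 0.5) == 1)
  list(time = time, event = event, group = group)
}

ref_params <- c(a = 0.16, b = -1.37, sigma = 1.53)
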