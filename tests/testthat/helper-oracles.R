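# Independent brute-force oracles used to cross-check the package's
# statistical kernels. These deliberately avoid the code paths they verify.

# Two-sided Fisher exact p for a 2x2 table by direct summation over the
# hypergeometric support.
oracle_fisher_2x2 <- function(m) {
  k <- m[1, 1] + m[1, 2] # row 1 total
  n1 <- m[1, 1] + m[2, 1] # column 1 total
  n <- sum(m)
  a_range <- max(0, k - (n - n1)):min(k, n1)
  probs <- stats::dhyper(a_range, n1, n - n1, k)
  p_obs <- stats::dhyper(m[1, 1], n1, n - n1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact Mann-Whitney p by full enumeration over all assignments of the pooled
# values to the two groups; U computed from pairwise comparisons (with 0.5
# per tie), independent of any rank-sum identity.
oracle_mw <- function(x, y, alternative = "two.sided") {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Hand-rolled Benjamini-Hochberg step-up q-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- vapply(seq_len(m), function(i) {
    min(p[o][i:m] * m / (i:m))
  }, 0)
  pmin(q, 1)
}

# Gompertz OD evaluated independently from the package's parameterization.
oracle_gompertz_od <- function(t, od0, A, mu, lag) {
  od0 * exp(A * exp(-exp(mu * exp(1) / A * (lag - t) + 1)))
}

# Small deterministic growth curve fixture.
make_curve <- function(mu = 0.01, lag = 200, capacity = 0.5, od0 = 0.01,
                       noise_sd = 0, duration = 2000, seed = 1) {
  simulate_growth_curve(mu, lag, capacity, od0 = od0, noise_sd = noise_sd,
                        duration_min = duration, seed = seed)
}
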