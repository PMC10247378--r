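# Independent brute-force oracles used to verify the statistical
# primitives. These deliberately avoid the code paths of the functions
# they check (no wilcox.test / fisher.test / p.adjust).

# Exact two-sided Mann-Whitney p by enumeration of all rank placements
# (no ties assumed). U is the count of (x_i, y_j) pairs with x_i > y_j.
oracle_mw <- function(x, y) {
  m <- length(x); n <- length(y)
  u_obs <- sum(outer(x, y, ">"))
  pooled_ranks <- seq_len(m + n)
  placements <- utils::combn(m + n, m)
  u_all <- apply(placements, 2, function(ix) {
    # U for x = sum of x ranks - m(m+1)/2 when values are distinct
    sum(ix) - m * (m + 1) / 2
  })
  center <- m * n / 2
  p <- mean(abs(u_all - center) >= abs(u_obs - center))
  list(U = u_obs, p = p)
}

# Two-sided Fisher p: total hypergeometric probability of tables with
# probability <= observed (relative tolerance for floating-point ties).
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Step-wise multiple-testing oracles written directly from the
# definitions.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(o == i) # rank of p[i]
    adj[i] <- min(1, min(p[o][r:n] * n / (r:n)))
  }
  adj
}
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(o == i)
    adj[i] <- min(1, max(p[o][1:r] * (n - (1:r) + 1)))
  }
  adj
}
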