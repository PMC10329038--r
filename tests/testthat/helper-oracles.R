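# Independent oracles used to cross-check the package's implementations.
# Each is written as a direct transcription of the definition, with no code
# shared with the implementation under test.

# Exhaustive minimization over level sequences (branch-and-bound with an
# admissible per-position bound, so it provably returns the global optimum).
oracle_kleinberg <- function(x, lambda_bar, s, gamma, L) {
  n <- length(x)
  lam <- lambda_bar * s^(0:L)
  emit <- sapply(seq_len(n), function(t) -log(lam) + lam * x[t])
  emit <- matrix(emit, nrow = L + 1L)
  tc <- gamma * log(n)
  minsuf <- rev(cumsum(rev(apply(emit, 2, min))))
  best_cost <- Inf
  best_seq <- NULL
  rec <- function(t, prev, acc, seq) {
    bound <- if (t <= n) minsuf[t] else 0
    if (acc + bound >= best_cost) return()
    if (t > n) {
      best_cost <<- acc
      best_seq <<- seq
      return()
    }
    for (i in 0:L) {
      trans <- if (i > prev) (i - prev) * tc else 0
      rec(t + 1L, i, acc + trans + emit[i + 1L, t], c(seq, i))
    }
  }
  rec(1L, 0L, 0, integer(0))
  list(bl = best_seq, cost = best_cost)
}

# Plug-in transfer entropy (k = l = 1) by direct summation over all symbol
# triples, from empirical joint probabilities.
oracle_te <- function(source, target) {
  n <- length(target)
  a <- target[2:n]        # x_{t+1}
  b <- target[1:(n - 1)]  # x_t
  cc <- source[1:(n - 1)] # y_t
  M <- n - 1
  te <- 0
  for (va in unique(a)) for (vb in unique(b)) for (vc in unique(cc)) {
    p_abc <- sum(a == va & b == vb & cc == vc) / M
    if (p_abc == 0) next
    p_a_bc <- sum(a == va & b == vb & cc == vc) / sum(b == vb & cc == vc)
    p_a_b <- sum(a == va & b == vb) / sum(b == vb)
    te <- te + p_abc * log2(p_a_bc / p_a_b)
  }
  te
}

# Permutation distribution of the Brunner-Munzel statistic for two groups
# of sizes n1, n2 with continuous (tie-free) data. The studentized
# statistic of a permutation depends only on which sorted positions land in
# group A, so the whole distribution can be precomputed from the
# combinations of positions.
bm_perm_stats <- function(n1, n2) {
  N <- n1 + n2
  idx <- utils::combn(N, n1)          # sorted-position sets for group A
  nc <- ncol(idx)
  occ <- matrix(TRUE, N, nc)
  occ[cbind(as.vector(idx), rep(seq_len(nc), each = n1))] <- FALSE
  comp <- matrix(row(occ)[occ], nrow = n2)  # complement positions, sorted
  m1 <- colMeans(idx); m2 <- colMeans(comp)
  dev1 <- idx - seq_len(n1) - rep(m1, each = n1) + (n1 + 1) / 2
  dev2 <- comp - seq_len(n2) - rep(m2, each = n2) + (n2 + 1) / 2
  v1 <- colSums(dev1^2) / (n1 - 1)
  v2 <- colSums(dev2^2) / (n2 - 1)
  pooled <- n1 * v1 + n2 * v2
  stat <- ifelse(pooled > 0,
                 n1 * n2 * (m2 - m1) / N / sqrt(pooled),
                 sign(m2 - m1) * Inf)
  stat
}

bm_perm_p <- function(a, b, all_stats) {
  obs <- brunner_munzel(a, b)$statistic
  mean(abs(all_stats) >= abs(obs) - 1e-10)
}

# Brute-force permutation p-value calling brunner_munzel on every label
# assignment (used to validate bm_perm_stats itself at small n).
bm_perm_p_brute <- function(a, b) {
  v <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(v), n1)
  obs <- abs(brunner_munzel(a, b)$statistic)
  stats <- apply(idx, 2, function(ii)
    abs(suppressWarnings(brunner_munzel(v[ii], v[-ii])$statistic)))
  mean(stats >= obs - 1e-10)
}
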