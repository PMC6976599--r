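# Independent oracles used to cross-check the package's statistical
# primitives and optimizer.  These deliberately re-derive each quantity
# from first principles and never call the implementation they check.

# Benjamini-Hochberg step-up rule, written out literally: sort, scale by
# m/i, take the cumulative minimum from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Chi-square upper tail for even degrees of freedom, by the closed-form
# series P(X > x) = exp(-x/2) * sum_{i=0}^{k-1} (x/2)^i / i!  (df = 2k).
oracle_chisq_tail_even <- function(x, df) {
  stopifnot(df %% 2 == 0)
  k <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

oracle_fisher <- function(p) {
  oracle_chisq_tail_even(-2 * sum(log(p)), 2 * length(p))
}

# Hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Membership-frequency oracle for robustness/specificity scoring.
oracle_frequency <- function(runs, id) {
  mean(vapply(runs, function(r) id %in% r, TRUE))
}
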