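## Independent brute-force oracles used to validate the package's
## statistical routes.  These deliberately avoid the code paths (and
## where possible the stats functions) they are checking.

## Benjamini-Hochberg step-up, computed literally from the definition:
## q_(i) = min_{j >= i} (n / j) p_(j), on the sorted p-values.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

## Two-sided Fisher exact p by exhaustive enumeration of the
## hypergeometric support, summing the probability of every table at
## most as likely as the observed one (same relative slack as R's
## convention).
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, n1 - m2):min(m1, n1)
  pk <- choose(m1, ks) * choose(m2, n1 - ks) / choose(m1 + m2, n1)
  p_obs <- pk[ks == a]
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

## Upper-tail hypergeometric by direct summation.
hyper_enum_oracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js) / choose(N, n))
}

## Upper-tail binomial by direct pmf summation.
binom_tail_oracle <- function(x, n, r) {
  ks <- x:n
  sum(choose(n, ks) * r^ks * (1 - r)^(n - ks))
}
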