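# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths they check.

# upper binomial tail P(X >= x) by direct summation of the pmf
oracle_binom_upper <- function(x, n, p) {
  k <- x:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# two-sided Fisher exact p by hypergeometric enumeration over the support
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U of group x vs y by direct pair counting (ties half)
oracle_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# exact two-sided permutation p for the U statistic by full enumeration
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- oracle_u_stat(x, y)
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2, function(idx) {
    oracle_u_stat(pooled[idx], pooled[-idx])
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# quartile by linear interpolation between order statistics (type 7 rule),
# written out longhand
oracle_quartile <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Clopper-Pearson bounds by inverting the binomial tails with uniroot
oracle_cp_interval <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else {
    stats::uniroot(function(p) {
      sum(stats::dbinom(x:n, n, p)) - alpha / 2
    }, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (x == n) 1 else {
    stats::uniroot(function(p) {
      sum(stats::dbinom(0:x, n, p)) - alpha / 2
    }, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower, upper)
}

# helper: build a karyotype set from a logical strains x chromosomes
# aneuploidy indicator matrix on a haploid base; deviations cycle over
# +1..+3 (wider for heavily aneuploid strains) so the modal copy number is
# always 1 and never ties
karyotype_set_from_indicators <- function(aneu, label = "sim") {
  ks <- lapply(seq_len(nrow(aneu)), function(i) {
    idx <- which(aneu[i, ])
    span <- if (length(idx) <= 11) 3L else 7L
    copies <- rep(1L, 16L)
    copies[idx] <- 1L + 1L + (seq_along(idx) - 1L) %% span
    karyotype(sprintf("%s_%03d", label, i),
              stats::setNames(copies, CHROMOSOMES))
  })
  karyotype_set(ks, label = label)
}
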