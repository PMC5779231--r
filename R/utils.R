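# Internal helpers shared across modules.

# round to nearest integer, ties away from zero (base round() ties to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)` of the proportion interval.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# deterministic per-generator seed derived from the master seed, so that
# adding one generator never perturbs the random stream of another
substream_seed <- function(seed, stream) {
  offsets <- c(
    meiosis = 1L, cells = 2L, lineage = 3L, loci = 4L,
    counts = 5L, qpcr = 6L, dna = 7L, annotations = 8L
  )
  if (!stream %in% names(offsets)) {
    stop("unknown random substream: ", stream)
  }
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stream]] * 7919L
}
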