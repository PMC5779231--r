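#' Summarize per-pixel intensities into a per-cell measurement
#'
#' Upstream image processing (background subtraction, sum projection) is
#' assumed done; this helper reduces a pixel list to the per-cell summary the
#' rest of the module consumes. The standard deviation uses the population
#' (divide by n) convention.
#'
#' @param values Numeric vector of background-subtracted pixel intensities.
#' @param cell_id Optional cell identifier carried through.
#' @return List with `mean_intensity`, `sd_intensity`, `n_pixels`,
#'   and `cell_id`.
#' @export
summarize_pixels <- function(values, cell_id = NA_character_) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  list(cell_id = cell_id,
       mean_intensity = mean(values),
       sd_intensity = pop_sd(values),
       n_pixels = length(values))
}

#' Coefficient of variation of fluorescence pixel intensity
#'
#' CV = standard deviation / mean of per-pixel intensity over the whole-cell
#' sum projection. A low CV indicates diffuse signal; sharply localized
#' Sir2 foci give a high CV.
#'
#' @param mean_intensity,sd_intensity Per-cell summaries (vectorized).
#' @return Numeric vector of dimensionless CV values.
#' @export
coefficient_of_variation <- function(mean_intensity, sd_intensity) {
  if (any(mean_intensity <= 0)) {
    stop("CV undefined: mean_intensity must be > 0")
  }
  if (any(sd_intensity < 0)) stop("sd_intensity must be >= 0")
  sd_intensity / mean_intensity
}

#' Tukey upper outlier fence of a wild-type intensity distribution
#'
#' Returns Q3 + k * IQR with quartiles computed by linear interpolation
#' between order statistics (quantile type 7). Cells of a test strain whose
#' mean intensity exceeds this fence are called desilenced outliers relative
#' to the wild-type population.
#'
#' @param wt_intensities Numeric vector (>= 4 values) of wild-type per-cell
#'   mean intensities.
#' @param k Fence multiplier (default 1.5, Tukey's inner fence).
#' @return Threshold in the same arbitrary units as the input.
#' @export
tukey_high_fence <- function(wt_intensities, k = 1.5) {
  if (length(wt_intensities) < 4) {
    stop("need at least 4 wild-type values to place a fence")
  }
  q <- stats::quantile(wt_intensities, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + k * (q[2] - q[1])
}

#' Classify cells as desilenced against a fence
#'
#' A cell is labeled desilenced iff its mean intensity is strictly above the
#' fence; cells exactly at the fence count as silenced.
#'
#' @param intensities Numeric vector of per-cell mean intensities, or a
#'   data.frame with a `mean_intensity` column.
#' @param fence Threshold, typically from [tukey_high_fence()] on the
#'   wild-type strain.
#' @param conf Confidence level for the Clopper-Pearson interval on the
#'   desilenced fraction.
#' @return List with `desilenced` (logical per cell), `n`, `n_desilenced`,
#'   `fraction`, `ci_lower`, `ci_upper`.
#' @export
classify_desilenced <- function(intensities, fence, conf = 0.95) {
  if (is.data.frame(intensities)) intensities <- intensities$mean_intensity
  if (length(intensities) == 0) stop("no cells to classify")
  if (!is.finite(fence)) stop("fence must be finite")
  lab <- intensities > fence
  ci <- clopper_pearson(sum(lab), length(lab), conf)
  list(desilenced = lab, n = length(lab), n_desilenced = sum(lab),
       fraction = mean(lab),
       ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
}

#' Mann-Whitney U comparison of two intensity samples
#'
#' Computes the rank-sum U statistic and a two-sided p-value: by exhaustive
#' enumeration of all group labelings when both groups have at most
#' `exact_max` observations, and by the tie-corrected normal approximation
#' otherwise. The exact two-sided p-value is the permutation probability of a
#' U at least as far from its null mean n1*n2/2 as observed, which handles
#' ties without special cases.
#'
#' @param a,b Numeric vectors of per-cell mean intensities.
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return List with `U` (the smaller of U1, U2), `U1` (pairs where `a`
#'   exceeds `b`, ties half), `p`, `method` ("exact" or "normal"), and
#'   `degenerate` (TRUE when all values across both groups are identical, in
#'   which case p = 1).
#' @export
compare_intensity <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    return(list(U = n1 * n2 / 2, U1 = n1 * n2 / 2, p = 1,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= exact_max) {
    labelings <- utils::combn(N, n1)
    u_perm <- apply(labelings, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(u_perm - mu) >= abs(U1 - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U1 - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = min(U1, U2), U1 = U1, p = min(p, 1), method = method,
       degenerate = FALSE)
}

#' Desilencing score of a test strain
#'
#' Ratio of the mean reporter fluorescence of a test strain to that of the
#' control strain (the disome X strain carrying an empty vector in the
#' gain-of-function screen).
#'
#' @param test_mean,control_mean Mean YFP intensities (vectorized over
#'   `test_mean`).
#' @return Numeric score(s).
#' @export
desilencing_score <- function(test_mean, control_mean) {
  if (any(control_mean <= 0)) stop("control_mean must be > 0")
  test_mean / control_mean
}

#' Rank screen candidates by desilencing score
#'
#' @param scores Named numeric vector of desilencing scores (names = strain
#'   or gene identifiers).
#' @param top_n How many top-ranked candidates to retain (default 15, the
#'   verification cut used for the chromosome X gene screen); `Inf` keeps all.
#' @return data.frame with `id`, `score`, `rank`, ordered by descending
#'   score.
#' @export
rank_desilencing_scores <- function(scores, top_n = 15) {
  stopifnot(length(scores) > 0, !is.null(names(scores)))
  ord <- order(scores, decreasing = TRUE)
  out <- data.frame(id = names(scores)[ord], score = unname(scores[ord]),
                    rank = seq_along(scores))
  utils::head(out, n = top_n)
}

#' Detect silencing state transitions along a lineage trace
#'
#' A two-threshold (hysteresis) state machine over a fluorescence time
#' course: the lineage starts in the state of its first timepoint (on iff
#' intensity >= `on_threshold`), switches off-to-on when intensity rises to
#' `on_threshold` or above, and on-to-off when it falls to `off_threshold`
#' or below. Excursions inside the band produce no events.
#'
#' @param times Strictly increasing numeric timepoints (minutes).
#' @param intensities Mean intensity at each timepoint.
#' @param on_threshold,off_threshold Hysteresis thresholds; must satisfy
#'   `on_threshold > off_threshold`. Sensible defaults are a wild-type Tukey
#'   fence and the wild-type median, respectively.
#' @return data.frame with columns `time` and `direction` ("on" or "off"),
#'   in chronological order; zero rows for a monotone silenced trace.
#' @export
detect_transitions <- function(times, intensities, on_threshold,
                               off_threshold) {
  if (on_threshold <= off_threshold) {
    stop("on_threshold must exceed off_threshold (hysteresis band)")
  }
  stopifnot(length(times) == length(intensities), length(times) >= 1,
            all(diff(times) > 0))
  state_on <- intensities[1] >= on_threshold
  ev_time <- numeric(0); ev_dir <- character(0)
  for (i in seq_along(times)[-1]) {
    if (!state_on && intensities[i] >= on_threshold) {
      state_on <- TRUE
      ev_time <- c(ev_time, times[i]); ev_dir <- c(ev_dir, "on")
    } else if (state_on && intensities[i] <= off_threshold) {
      state_on <- FALSE
      ev_time <- c(ev_time, times[i]); ev_dir <- c(ev_dir, "off")
    }
  }
  data.frame(time = ev_time, direction = ev_dir)
}

#' Fraction of cells in G2 from a DNA-content sample
#'
#' Gates cells at the midpoint between the 1N (G1) and 2N (G2) modes of the
#' DNA-content histogram; cells above the boundary are counted as G2.
#'
#' @param values Per-cell DNA-content measurements (arbitrary units).
#' @param g1_position,g2_position Expected positions of the 1N and 2N modes;
#'   `g2_position` must exceed `g1_position`.
#' @return Percentage of cells in G2.
#' @export
g2_fraction <- function(values, g1_position, g2_position) {
  if (g1_position >= g2_position) {
    stop("g1_position must be below g2_position")
  }
  if (g1_position <= 0) stop("mode positions must be positive")
  if (length(values) == 0) stop("no cells")
  boundary <- (g1_position + g2_position) / 2
  100 * mean(values > boundary)
}

#' Aggregate G2 fractions across replicates
#'
#' @param percentages Numeric vector of per-replicate G2 percentages, e.g.
#'   from repeated [g2_fraction()] calls.
#' @return List with `mean` and `sd` (sample sd across replicates).
#' @export
g2_fraction_summary <- function(percentages) {
  stopifnot(length(percentages) >= 1)
  list(mean = mean(percentages),
       sd = if (length(percentages) > 1) stats::sd(percentages) else NA_real_)
}
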