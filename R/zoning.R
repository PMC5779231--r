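#' Relative radii of the three equal-area nuclear zones
#'
#' The nuclear cross-section is divided into three concentric zones of equal
#' area: zone 1 at the nuclear envelope, zone 2 medial, zone 3 central. In
#' the planar (default) geometry the boundaries fall at relative radii
#' sqrt(1/3) and sqrt(2/3); the 3D spherical-shell variant (equal volumes)
#' places them at (1/3)^(1/3) and (2/3)^(1/3).
#'
#' @param geometry `"area"` (planar cross-section, default) or `"volume"`
#'   (spherical shells).
#' @return Numeric vector `c(inner, mid)` of relative boundary radii.
#' @export
zone_boundaries <- function(geometry = c("area", "volume")) {
  geometry <- match.arg(geometry)
  if (geometry == "area") c(sqrt(1 / 3), sqrt(2 / 3))
  else c((1 / 3)^(1 / 3), (2 / 3)^(1 / 3))
}

#' Zone of a single tagged-locus observation
#'
#' @param locus_x,locus_y Locus coordinates.
#' @param center_x,center_y Nuclear center.
#' @param radius Nuclear radius (> 0), same units as the coordinates.
#' @param tolerance Loci up to `tolerance * radius` outside the fitted
#'   nuclear circle are clamped to the envelope (zone 1); farther ones are an
#'   error. Default 0.05, absorbing segmentation jitter at the envelope
#'   marker.
#' @param geometry Passed to [zone_boundaries()].
#' @return Integer zone: 1 = peripheral/NE, 2 = medial, 3 = central.
#'   Boundary points are assigned to the more central zone (`<=` rule).
#' @export
zone_of <- function(locus_x, locus_y, center_x, center_y, radius,
                    tolerance = 0.05, geometry = "area") {
  classify_zones(data.frame(cell_id = "cell", center_x = center_x,
                            center_y = center_y, radius = radius,
                            locus_x = locus_x, locus_y = locus_y),
                 tolerance = tolerance, geometry = geometry)$zone
}

#' Classify tagged-locus positions into the three nuclear zones
#'
#' @param loci data.frame with columns `center_x`, `center_y`, `radius`,
#'   `locus_x`, `locus_y` (and optionally `cell_id`); units arbitrary but
#'   consistent within a row.
#' @inheritParams zone_of
#' @return The input data.frame with added columns `rho` (relative radial
#'   position, clamped to 1 within tolerance) and `zone`.
#' @export
classify_zones <- function(loci, tolerance = 0.05, geometry = "area") {
  stopifnot(is.data.frame(loci))
  needed <- c("center_x", "center_y", "radius", "locus_x", "locus_y")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols) > 0) {
    stop("locus table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(loci$radius <= 0)) stop("nuclear radius must be > 0")
  d <- sqrt((loci$locus_x - loci$center_x)^2 +
              (loci$locus_y - loci$center_y)^2)
  rho <- d / loci$radius
  out_of_bounds <- rho > 1 + tolerance
  if (any(out_of_bounds)) {
    stop(sum(out_of_bounds), " locus observation(s) lie more than ",
         tolerance * 100, "% of the radius outside the nucleus")
  }
  rho <- pmin(rho, 1)
  b <- zone_boundaries(geometry)
  zone <- ifelse(rho <= b[1], 3L, ifelse(rho <= b[2], 2L, 1L))
  loci$rho <- rho
  loci$zone <- zone
  loci
}

#' Zone counts and percentages
#'
#' @param zones Integer vector of zone labels in `{1, 2, 3}`, or a
#'   data.frame from [classify_zones()].
#' @return List with `counts` (named n1/n2/n3, zone 1 = peripheral) and
#'   `percent` (summing to 100 up to rounding of the inputs).
#' @export
zone_distribution <- function(zones) {
  if (is.data.frame(zones)) zones <- zones$zone
  if (length(zones) == 0) stop("no observations")
  stopifnot(all(zones %in% 1:3))
  counts <- vapply(1:3, function(z) sum(zones == z), integer(1))
  names(counts) <- c("n1", "n2", "n3")
  list(counts = counts, percent = 100 * counts / sum(counts))
}

#' Chi-square test of zone counts against the uniform null
#'
#' Pearson chi-square of the three zone counts against equal expected counts
#' (the "random, 33% per zone" null), with 2 degrees of freedom, optionally
#' accompanied by a Monte-Carlo p-value from multinomial resampling for
#' small totals.
#'
#' @param counts Length-3 vector of zone counts (or the `counts` element of
#'   [zone_distribution()]).
#' @param mc_reps Number of multinomial resamples for the Monte-Carlo p
#'   (0 = analytic only).
#' @param seed Optional seed for the resampling.
#' @return List with `statistic`, `df`, `p_analytic`, and `p_mc` (NA when
#'   `mc_reps = 0`). The Monte-Carlo p uses the add-one rule
#'   (1 + #{sim >= obs}) / (reps + 1).
#' @export
chi_square_uniform <- function(counts, mc_reps = 0, seed = NULL) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("zone counts are all zero")
  expected <- rep(total / 3, 3)
  statistic <- sum((counts - expected)^2 / expected)
  p_analytic <- stats::pchisq(statistic, df = 2, lower.tail = FALSE)
  p_mc <- NA_real_
  if (mc_reps > 0) {
    sim_stat <- function() {
      x <- as.numeric(stats::rmultinom(1, total, rep(1 / 3, 3)))
      sum((x - expected)^2 / expected)
    }
    draw <- function() {
      sims <- replicate(mc_reps, sim_stat())
      (1 + sum(sims >= statistic - 1e-12)) / (mc_reps + 1)
    }
    p_mc <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  list(statistic = statistic, df = 2, p_analytic = p_analytic, p_mc = p_mc)
}

#' Peripheral (zone 1) fraction with exact confidence interval
#'
#' @param counts Length-3 vector of zone counts (zone 1 first).
#' @param conf Confidence level.
#' @return List with `fraction`, `ci_lower`, `ci_upper`, `n`.
#' @export
peripheral_fraction <- function(counts, conf = 0.95) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("zone counts are all zero")
  ci <- clopper_pearson(counts[1], total, conf)
  list(fraction = counts[1] / total,
       ci_lower = ci[["lower"]], ci_upper = ci[["upper"]], n = total)
}
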