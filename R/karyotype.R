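#' Construct a karyotype
#'
#' A karyotype is a per-chromosome copy-number vector for one strain,
#' optionally annotated with its silencing phenotype.
#'
#' @param strain_id Strain identifier.
#' @param copies Integer vector of length 16 giving the copy number of each
#'   chromosome. If unnamed, taken in `chrI`..`chrXVI` order; if named, names
#'   must cover all of [CHROMOSOMES].
#' @param phenotype Optional logical: `TRUE` if the strain is desilenced,
#'   `FALSE` if silenced, `NA` if unknown.
#' @return An object of class `"karyotype"`.
#' @examples
#' k <- karyotype("disX", c(chrX = 2), base = 1)
#' basal_ploidy(k)
#' aneuploid_chromosomes(k)
#' @param base Convenience: copy number assigned to chromosomes absent from a
#'   partially named `copies` vector (so `c(chrX = 2)` with `base = 1`
#'   describes disome X). Ignored when all 16 chromosomes are given.
#' @export
karyotype <- function(strain_id, copies, phenotype = NA, base = NULL) {
  if (is.null(names(copies))) {
    if (length(copies) != 16L) {
      stop("unnamed `copies` must have length 16")
    }
    names(copies) <- CHROMOSOMES
  } else {
    names(copies) <- as.character(normalize_chromosome(names(copies)))
    if (!is.null(base)) {
      full <- stats::setNames(rep(as.integer(base), 16L), CHROMOSOMES)
      full[names(copies)] <- copies
      copies <- full
    }
  }
  missing <- setdiff(CHROMOSOMES, names(copies))
  if (length(missing) > 0) {
    stop("karyotype is missing chromosomes: ", paste(missing, collapse = ", "))
  }
  copies <- as.integer(copies[CHROMOSOMES])
  if (any(is.na(copies)) || any(copies < 0)) {
    stop("copy numbers must be non-negative integers")
  }
  if (all(copies < 1)) {
    stop("at least one chromosome must have copy number >= 1")
  }
  names(copies) <- CHROMOSOMES
  structure(
    list(strain_id = as.character(strain_id), copies = copies,
         phenotype = as.logical(phenotype)),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  cat("Karyotype of strain", x$strain_id, "\n")
  bp <- tryCatch(basal_ploidy(x), error = function(e) NA_integer_)
  cat("  basal ploidy:", bp, "\n")
  dev <- if (is.na(bp)) NULL else aneuploid_chromosomes(x)
  if (is.null(dev)) {
    cat("  basal ploidy tied; aneuploidies undefined\n")
  } else if (length(dev) == 0) {
    cat("  euploid\n")
  } else {
    cat("  aneuploid:", paste(sprintf("%s %+d", names(dev), dev),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Basal ploidy of a karyotype
#'
#' The basal ploidy is the copy number possessed by most chromosomes; all
#' chromosomes deviating from it are called aneuploid.
#'
#' @param k A [karyotype()].
#' @return Integer modal copy number.
#' @details An exact tie between two modal copy numbers (e.g. eight
#'   chromosomes at 2 and eight at 3) leaves the basal ploidy undefined; the
#'   function raises an error of class `"basal_ploidy_tie"` carrying the tied
#'   candidates in its `candidates` field rather than guessing.
#' @export
basal_ploidy <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  tab <- table(k$copies)
  modal <- as.integer(names(tab)[tab == max(tab)])
  if (length(modal) > 1) {
    cond <- structure(
      class = c("basal_ploidy_tie", "error", "condition"),
      list(message = paste0(
             "basal ploidy tie in strain ", k$strain_id, ": copy numbers ",
             paste(modal, collapse = " and "),
             " are each carried by ", max(tab), " chromosomes"),
           call = sys.call(-1), candidates = modal)
    )
    stop(cond)
  }
  modal
}

#' Aneuploid chromosomes of a karyotype
#'
#' @param k A [karyotype()].
#' @return Named integer vector of signed deviations from the basal ploidy
#'   for every aneuploid chromosome; empty if and only if euploid.
#' @export
aneuploid_chromosomes <- function(k) {
  bp <- basal_ploidy(k)
  dev <- k$copies - bp
  dev[dev != 0L]
}

#' Construct a set of karyotypes
#'
#' @param karyotypes List of [karyotype()] objects.
#' @param label Label for the set (e.g. `"desilenced"`, `"reference"`).
#' @return Object of class `"karyotype_set"` (a list of karyotypes with a
#'   label attribute).
#' @export
karyotype_set <- function(karyotypes, label = "") {
  stopifnot(all(vapply(karyotypes, inherits, logical(1), "karyotype")))
  ids <- vapply(karyotypes, function(k) k$strain_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate strain_id in karyotype set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(karyotypes, label = label, class = "karyotype_set")
}

#' @export
print.karyotype_set <- function(x, ...) {
  cat("Karyotype set", sQuote(attr(x, "label")), "with", length(x),
      "strains\n")
  invisible(x)
}

#' Convert a karyotype set to its CSV table form
#'
#' @param s A [karyotype_set()].
#' @return data.frame with columns `strain_id`, `chrI`..`chrXVI`,
#'   `phenotype` (0/1/NA).
#' @export
as.data.frame.karyotype_set <- function(x, ...) {
  df <- do.call(rbind, lapply(x, function(k) {
    data.frame(strain_id = k$strain_id, t(k$copies),
               phenotype = ifelse(is.na(k$phenotype), NA_integer_,
                                  as.integer(k$phenotype)),
               check.names = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Build a karyotype set from a karyotype table
#'
#' @param df data.frame with columns `strain_id`, `chrI`..`chrXVI` and
#'   optionally `phenotype` (0/1/NA).
#' @param label Set label.
#' @return A [karyotype_set()].
#' @export
as_karyotype_set <- function(df, label = "") {
  stopifnot(is.data.frame(df), "strain_id" %in% names(df))
  missing <- setdiff(CHROMOSOMES, names(df))
  if (length(missing) > 0) {
    stop("karyotype table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  has_phen <- "phenotype" %in% names(df)
  ks <- lapply(seq_len(nrow(df)), function(i) {
    phen <- if (has_phen) df$phenotype[i] else NA
    karyotype(df$strain_id[i],
              stats::setNames(as.integer(unlist(df[i, CHROMOSOMES])),
                              CHROMOSOMES),
              phenotype = if (is.na(phen)) NA else as.logical(phen))
  })
  karyotype_set(ks, label = label)
}

#' Count aneuploid occurrences of each chromosome across a strain set
#'
#' For each of the sixteen chromosomes, counts in how many strains of the set
#' that chromosome deviates from the strain's basal ploidy.
#'
#' @param s A [karyotype_set()].
#' @param gains_only If `TRUE`, count only positive deviations (copy-number
#'   gains); default counts any deviation.
#' @return Named integer vector over [CHROMOSOMES].
#' @export
gain_counts <- function(s, gains_only = FALSE) {
  stopifnot(inherits(s, "karyotype_set"))
  if (length(s) == 0) stop("empty karyotype set")
  counts <- stats::setNames(integer(16L), CHROMOSOMES)
  for (k in s) {
    dev <- aneuploid_chromosomes(k)
    if (gains_only) dev <- dev[dev > 0]
    counts[names(dev)] <- counts[names(dev)] + 1L
  }
  counts
}

#' Per-chromosome aneuploidy enrichment between two strain sets
#'
#' Tests, chromosome by chromosome, whether aneuploidy of that chromosome is
#' overrepresented in a phenotype-positive case set relative to the frequency
#' observed in a reference set of stable aneuploids, using an exact binomial
#' test.
#'
#' @param case,reference [karyotype_set()] objects; the reference supplies the
#'   per-chromosome null frequency.
#' @param side `"upper"` (overrepresentation, default) or `"two"` for a
#'   two-sided exact binomial test.
#' @param gains_only Passed to [gain_counts()]; count only copy-number gains.
#' @return data.frame with one row per chromosome: `chromosome`,
#'   `case_count`, `case_n`, `reference_count`, `reference_n`,
#'   `reference_freq`, `p_raw`, `p_adjusted` (Benjamini-Hochberg over the 16
#'   chromosomes).
#' @details When a chromosome is never aneuploid in the reference set its
#'   frequency is replaced by the half-count pseudofrequency
#'   `0.5 / n_reference` so the upper-tail probability is computable.
#'   Raw p-values are the exact binomial tail
#'   \eqn{\sum_{k \ge x} \binom{n}{k} p^k (1-p)^{n-k}}; adjusted p-values are
#'   reported alongside.
#' @export
enrichment_test <- function(case, reference, side = c("upper", "two"),
                            gains_only = FALSE) {
  side <- match.arg(side)
  stopifnot(inherits(case, "karyotype_set"),
            inherits(reference, "karyotype_set"))
  if (length(case) == 0 || length(reference) == 0) {
    stop("case and reference sets must be non-empty")
  }
  case_counts <- gain_counts(case, gains_only = gains_only)
  ref_counts <- gain_counts(reference, gains_only = gains_only)
  n_case <- length(case)
  n_ref <- length(reference)
  ref_freq <- ref_counts / n_ref
  ref_freq[ref_freq == 0] <- 0.5 / n_ref
  p_raw <- vapply(CHROMOSOMES, function(chr) {
    x <- case_counts[[chr]]
    p <- ref_freq[[chr]]
    if (side == "upper") {
      stats::pbinom(x - 1L, n_case, p, lower.tail = FALSE)
    } else {
      stats::binom.test(x, n_case, p, alternative = "two.sided")$p.value
    }
  }, numeric(1))
  data.frame(
    chromosome = CHROMOSOMES,
    case_count = as.integer(case_counts),
    case_n = n_case,
    reference_count = as.integer(ref_counts),
    reference_n = n_ref,
    reference_freq = as.numeric(ref_freq),
    p_raw = as.numeric(p_raw),
    p_adjusted = stats::p.adjust(p_raw, method = "BH"),
    row.names = NULL
  )
}

#' Screen hit rate with exact confidence interval
#'
#' @param n_positive Number of phenotype-positive colonies.
#' @param n_total Total colonies screened.
#' @param conf Confidence level for the Clopper-Pearson interval.
#' @return List with `percent`, `ci_lower`, `ci_upper` (all in percent),
#'   `n_positive`, `n_total`.
#' @examples
#' screen_rate(98, 3418)   # ~2.87%, "roughly 3%"
#' @export
screen_rate <- function(n_positive, n_total, conf = 0.95) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_positive < 0 || n_positive > n_total) {
    stop("n_positive must lie in [0, n_total]")
  }
  ci <- clopper_pearson(n_positive, n_total, conf)
  list(percent = 100 * n_positive / n_total,
       ci_lower = 100 * ci[["lower"]],
       ci_upper = 100 * ci[["upper"]],
       n_positive = n_positive, n_total = n_total)
}

#' Call a karyotype from qPCR Ct measurements
#'
#' Relative DNA quantity per chromosome is computed by the delta-delta-Ct
#' method, `efficiency^(-ddCt)` with
#' `ddCt = (ct_target - ct_reference) - calibrator_delta_ct`, averaged over
#' replicates; the copy number is the basal ploidy scaled by that quantity,
#' rounded to the nearest integer (ties away from zero).
#'
#' @param records data.frame with columns `strain_id`, `chromosome`,
#'   `ct_target`, `ct_reference`, `calibrator_delta_ct` (one row per
#'   replicate; a `replicate` column is allowed and ignored). All rows must
#'   belong to one strain.
#' @param basal Basal ploidy of the strain (>= 1).
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @param ambiguous_margin Calls whose pre-rounding value lies farther than
#'   this from the nearest integer are flagged ambiguous (default 0.35).
#' @return A [karyotype()] with attribute `"ambiguous"` (named logical over
#'   chromosomes) and `"relative_quantity"` (the unrounded basal-scaled
#'   quantities).
#' @export
call_copy_number_qpcr <- function(records, basal, efficiency = 2,
                                  ambiguous_margin = 0.35) {
  stopifnot(is.data.frame(records), basal >= 1)
  needed <- c("strain_id", "chromosome", "ct_target", "ct_reference",
              "calibrator_delta_ct")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("qPCR records are missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(unique(records$strain_id)) != 1) {
    stop("records must belong to a single strain; see the per-strain wrapper")
  }
  if (!all(is.finite(records$ct_target)) ||
      !all(is.finite(records$ct_reference))) {
    stop("Ct values must be finite")
  }
  chrom <- as.character(normalize_chromosome(records$chromosome))
  absent <- setdiff(CHROMOSOMES, chrom)
  if (length(absent) > 0) {
    stop("no qPCR records for chromosomes: ", paste(absent, collapse = ", "))
  }
  ddct <- (records$ct_target - records$ct_reference) -
    records$calibrator_delta_ct
  rq <- tapply(efficiency^(-ddct), chrom, mean)[CHROMOSOMES]
  scaled <- basal * rq
  copies <- as.integer(round_half_away(scaled))
  ambiguous <- abs(scaled - round_half_away(scaled)) > ambiguous_margin
  k <- karyotype(records$strain_id[1],
                 stats::setNames(copies, CHROMOSOMES))
  attr(k, "ambiguous") <- stats::setNames(as.logical(ambiguous), CHROMOSOMES)
  attr(k, "relative_quantity") <- stats::setNames(as.numeric(scaled),
                                                  CHROMOSOMES)
  k
}

#' Call karyotypes for every strain in a qPCR table
#'
#' @inheritParams call_copy_number_qpcr
#' @param label Label for the returned set.
#' @return A [karyotype_set()].
#' @export
call_karyotypes_qpcr <- function(records, basal, efficiency = 2,
                                 ambiguous_margin = 0.35, label = "qpcr") {
  ks <- lapply(split(records, records$strain_id), call_copy_number_qpcr,
               basal = basal, efficiency = efficiency,
               ambiguous_margin = ambiguous_margin)
  karyotype_set(unname(ks), label = label)
}
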