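#' Validate and complete a gene annotation table
#'
#' @param df data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`; 1-based inclusive coordinates. Derived columns `tss`
#'   (start for `+` strand, end for `-`) and `length` (end - start + 1) are
#'   added (or checked if present).
#' @return The completed data.frame.
#' @export
gene_annotations <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$start < 1) || any(df$end < df$start)) {
    stop("require 1 <= start <= end")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$chromosome <- as.character(normalize_chromosome(df$chromosome))
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$length <- df$end - df$start + 1L
  df
}

#' Relative copy profile of a karyotype
#'
#' @param k A [karyotype()].
#' @return Named numeric vector over [CHROMOSOMES] of copy number divided by
#'   basal ploidy (all 1 for a euploid).
#' @export
copy_profile <- function(k) {
  k$copies / basal_ploidy(k)
}

#' Normalize a count table to chromosome copy number
#'
#' Divides each gene's raw count by the relative copy number (chromosome
#' copies over basal ploidy) of its chromosome in the corresponding sample,
#' so pure dosage effects cancel. Euploid samples pass through unchanged.
#'
#' @param counts Numeric matrix, genes x samples, rownames = gene ids.
#' @param annotations Annotation table from [gene_annotations()] covering all
#'   row names of `counts`.
#' @param copy_ratios Numeric matrix, samples x chromosomes: relative copy
#'   number of each chromosome in each sample (rownames must cover
#'   `colnames(counts)`; see [copy_profile()]). A single named vector is
#'   recycled across samples.
#' @return Matrix of normalized counts with the same dimnames.
#' @export
normalize_counts <- function(counts, annotations, copy_ratios) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (is.vector(copy_ratios)) {
    copy_ratios <- matrix(copy_ratios, nrow = ncol(counts),
                          ncol = length(copy_ratios), byrow = TRUE,
                          dimnames = list(colnames(counts),
                                          names(copy_ratios)))
  }
  gene_chrom <- annotations$chromosome[match(rownames(counts),
                                             annotations$gene_id)]
  if (any(is.na(gene_chrom))) {
    stop("genes absent from annotations: ",
         paste(utils::head(rownames(counts)[is.na(gene_chrom)], 5),
               collapse = ", "))
  }
  missing_samples <- setdiff(colnames(counts), rownames(copy_ratios))
  if (length(missing_samples) > 0) {
    stop("no copy profile for sample(s): ",
         paste(missing_samples, collapse = ", "))
  }
  out <- counts
  for (s in colnames(counts)) {
    ratios <- copy_ratios[s, ]
    absent <- setdiff(unique(gene_chrom), colnames(copy_ratios))
    if (length(absent) > 0) {
      stop("sample ", s, ": no copy ratio for chromosome(s) ",
           paste(absent, collapse = ", "),
           " (first affected gene: ",
           rownames(counts)[match(absent[1], gene_chrom)], ")")
    }
    if (any(ratios <= 0, na.rm = TRUE)) stop("copy ratios must be > 0")
    out[, s] <- counts[, s] / as.numeric(ratios[gene_chrom])
  }
  out
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM = count * 1e9 / (gene length in bp * library size). The expression
#' gate used throughout downstream comparisons is strict: a gene is
#' expressed iff RPKM > 1.
#'
#' @param counts Genes x samples matrix (raw counts).
#' @param annotations Annotation table supplying gene lengths.
#' @param library_size Per-sample library sizes; defaults to column sums of
#'   the raw counts.
#' @return List with matrices `rpkm` and `expressed` (logical, RPKM > 1).
#' @export
rpkm <- function(counts, annotations,
                 library_size = colSums(counts)) {
  stopifnot(is.matrix(counts))
  if (any(library_size <= 0)) stop("library sizes must be > 0")
  len <- annotations$length[match(rownames(counts), annotations$gene_id)]
  if (any(is.na(len)) || any(len <= 0)) {
    stop("every gene needs a positive annotated length")
  }
  r <- sweep(counts * 1e9 / len, 2, library_size, "/")
  list(rpkm = r, expressed = r > 1)
}

#' Categorize genes as up- or down-regulated between two conditions
#'
#' Per-gene fold change is the ratio of mean normalized counts
#' (case / control, with a pseudocount added to both means); significance
#' comes from a per-gene moderated t-test on log2(normalized count +
#' pseudocount) (limma with a mean-variance trend), Benjamini-Hochberg
#' adjusted across the tested genes. A gene is "up" iff fold change >=
#' `fc_threshold` and adjusted p < `p_threshold`; "down" symmetrically at
#' 1/`fc_threshold`; otherwise "neither". This replicate-based test on
#' log-counts is a declared stand-in for a full negative-binomial
#' differential-expression fit and is documented as such.
#'
#' @param norm_counts Copy-number-normalized genes x samples matrix (see
#'   [normalize_counts()]).
#' @param condition Character/factor per column of `norm_counts` with
#'   exactly two levels.
#' @param case,control The two condition levels to contrast (fold change =
#'   case over control).
#' @param fc_threshold,p_threshold Gates (defaults 1.5 and 0.01).
#' @param pseudocount Added before log and to the fold-change means
#'   (default 0.5).
#' @param genes Optional character vector restricting the tested genes (e.g.
#'   genes expressed in both strains); BH adjustment runs over this set only.
#' @return data.frame with `gene_id`, `fold_change`, `log2_fc`, `p_raw`,
#'   `p_adjusted`, `category`.
#' @export
de_categorize <- function(norm_counts, condition, case, control,
                          fc_threshold = 1.5, p_threshold = 0.01,
                          pseudocount = 0.5, genes = NULL) {
  stopifnot(is.matrix(norm_counts), length(condition) == ncol(norm_counts))
  i_case <- which(condition == case)
  i_ctrl <- which(condition == control)
  if (length(i_case) < 2 || length(i_ctrl) < 2) {
    stop("need >= 2 replicates per condition for a dispersion estimate")
  }
  if (!is.null(genes)) {
    norm_counts <- norm_counts[rownames(norm_counts) %in% genes, ,
                               drop = FALSE]
  }
  x <- log2(norm_counts + pseudocount)
  m1 <- rowMeans(x[, i_case, drop = FALSE])
  m2 <- rowMeans(x[, i_ctrl, drop = FALSE])
  resid_sd <- sqrt(rowSums((x[, i_case, drop = FALSE] - m1)^2) +
                     rowSums((x[, i_ctrl, drop = FALSE] - m2)^2))
  if (all(resid_sd == 0)) {
    # no within-condition variation anywhere: exact-tie convention
    p <- ifelse(m1 == m2, 1, 0)
  } else {
    design <- cbind(intercept = 1,
                    case = as.integer(condition == case)[c(i_case, i_ctrl)])
    fit <- limma::lmFit(x[, c(i_case, i_ctrl), drop = FALSE], design)
    fit <- limma::eBayes(fit, trend = TRUE)
    p <- fit$p.value[, "case"]
  }
  fc <- (rowMeans(norm_counts[, i_case, drop = FALSE]) + pseudocount) /
    (rowMeans(norm_counts[, i_ctrl, drop = FALSE]) + pseudocount)
  padj <- stats::p.adjust(p, method = "BH")
  category <- rep("neither", nrow(norm_counts))
  category[fc >= fc_threshold & padj < p_threshold] <- "up"
  category[fc <= 1 / fc_threshold & padj < p_threshold] <- "down"
  data.frame(gene_id = rownames(norm_counts), fold_change = as.numeric(fc),
             log2_fc = log2(as.numeric(fc)), p_raw = as.numeric(p),
             p_adjusted = as.numeric(padj), category = category,
             row.names = NULL)
}

#' Assign ChIP peaks to the gene with the nearest transcription start site
#'
#' Each peak is assigned to the gene whose TSS is closest to the peak
#' interval (distance 0 if the TSS lies inside the peak, otherwise the
#' smaller endpoint distance); the assignment is kept only when that
#' distance is at most `max_distance`. When several peaks land on one gene,
#' their scores are combined by `combine` (default: maximum).
#'
#' @param peaks data.frame with columns `chromosome`, `start`, `end`,
#'   `score` (peak score, -log10 q-value).
#' @param annotations Annotation table from [gene_annotations()].
#' @param max_distance Maximum TSS distance in bp (default 600).
#' @param combine `"max"` or `"sum"` for multi-peak genes.
#' @return data.frame with `gene_id`, `score`, `n_peaks`; attribute
#'   `"report"` lists peaks skipped for unannotated chromosomes and peaks
#'   dropped by the distance filter.
#' @export
map_peaks_to_genes <- function(peaks, annotations, max_distance = 600,
                               combine = c("max", "sum")) {
  combine <- match.arg(combine)
  stopifnot(is.data.frame(peaks),
            all(c("chromosome", "start", "end", "score") %in% names(peaks)))
  peaks$chromosome <- as.character(peaks$chromosome)
  known <- peaks$chromosome %in% annotations$chromosome
  if (any(!known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from the ",
            "annotations were skipped")
  }
  kept_gene <- character(0); kept_score <- numeric(0)
  n_dropped <- 0L
  for (i in which(known)) {
    ann <- annotations[annotations$chromosome == peaks$chromosome[i], ]
    inside <- ann$tss >= peaks$start[i] & ann$tss <= peaks$end[i]
    dist <- ifelse(inside, 0,
                   pmin(abs(peaks$start[i] - ann$tss),
                        abs(peaks$end[i] - ann$tss)))
    j <- which.min(dist)   # ties broken by annotation order
    if (dist[j] <= max_distance) {
      kept_gene <- c(kept_gene, ann$gene_id[j])
      kept_score <- c(kept_score, peaks$score[i])
    } else {
      n_dropped <- n_dropped + 1L
    }
  }
  agg <- if (combine == "max") {
    tapply(kept_score, kept_gene, max)
  } else {
    tapply(kept_score, kept_gene, sum)
  }
  npk <- tapply(kept_score, kept_gene, length)
  out <- data.frame(gene_id = names(agg), score = as.numeric(agg),
                    n_peaks = as.integer(npk), row.names = NULL)
  attr(out, "report") <- list(n_skipped_chromosome = sum(!known),
                              n_dropped_distance = n_dropped,
                              n_assigned = length(kept_gene))
  out
}

#' Convert per-gene peak scores to Z-scores within a strain
#'
#' Scores must already be divided by the gene's chromosome copy ratio (see
#' [normalize_counts()] logic) so dosage does not masquerade as enrichment.
#' Standardization uses the population (divide by n) standard deviation over
#' the strain's scored genes.
#'
#' @param scores Named numeric vector, gene id -> copy-normalized peak score.
#' @return Named numeric vector of Z-scores (mean 0, population sd 1).
#' @export
zscore_scores <- function(scores) {
  stopifnot(!is.null(names(scores)))
  if (length(scores) < 2) stop("need >= 2 scored genes")
  s <- pop_sd(scores)
  if (s == 0) stop("degenerate score set: zero variance")
  (scores - mean(scores)) / s
}

#' Per-gene Z-score difference between two strains
#'
#' @param z_case,z_control Named Z-score vectors from [zscore_scores()]
#'   (e.g. disome and wild-type haploid).
#' @return Named numeric vector of case-minus-control differences over the
#'   genes scored in both strains.
#' @export
delta_z <- function(z_case, z_control) {
  common <- intersect(names(z_case), names(z_control))
  if (length(common) == 0) stop("no genes scored in both strains")
  z_case[common] - z_control[common]
}

#' Flag subtelomeric genes
#'
#' A gene is subtelomeric iff its distance to the nearer chromosome end,
#' `min(start - 1, chromosome_length - end)`, is strictly below the
#' threshold.
#'
#' @param annotations Annotation table from [gene_annotations()].
#' @param chrom_lengths Named chromosome lengths in bp (default
#'   [SACCER3_CHROM_LENGTHS]).
#' @param threshold Distance threshold in bp (default 25000).
#' @return Logical vector along the rows of `annotations`.
#' @export
flag_subtelomeric <- function(annotations,
                              chrom_lengths = SACCER3_CHROM_LENGTHS,
                              threshold = 25000) {
  len <- chrom_lengths[annotations$chromosome]
  if (any(is.na(len))) {
    stop("missing chromosome length for: ",
         paste(unique(annotations$chromosome[is.na(len)]), collapse = ", "))
  }
  if (any(annotations$end > len)) {
    stop("gene(s) extend beyond their chromosome length: ",
         paste(utils::head(
           annotations$gene_id[annotations$end > len], 5), collapse = ", "))
  }
  pmin(annotations$start - 1, len - annotations$end) < threshold
}

#' Fisher enrichment of one gene category within another
#'
#' Two-sided Fisher's exact test of the 2x2 table crossing a gene category
#' flag (e.g. subtelomeric) with a highlighted gene set (e.g. upregulated
#' with positive Z-score difference).
#'
#' @param flags,highlighted Logical vectors over the same genes.
#' @return List with `table` (2x2), `odds_ratio` (conditional MLE; `Inf`/0
#'   with `degenerate = TRUE` when a margin is empty), `p`, `degenerate`.
#' @export
fisher_category_enrichment <- function(flags, highlighted) {
  stopifnot(length(flags) == length(highlighted), length(flags) > 0)
  tab <- table(factor(flags, levels = c(TRUE, FALSE)),
               factor(highlighted, levels = c(TRUE, FALSE)),
               dnn = c("category", "highlighted"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    # an empty margin fixes the table given its margins: no evidence either way
    or <- if (tab[1, 1] > 0 && tab[2, 2] == 0) Inf else
      if (tab[1, 2] > 0 || tab[2, 1] > 0) 0 else NA_real_
    return(list(table = tab, odds_ratio = or, p = 1, degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  degenerate <- !is.finite(ft$estimate) || ft$estimate == 0
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       degenerate = degenerate)
}

#' Copy-number-normalized qPCR expression fold change
#'
#' Fold expression of a target gene in a strain relative to a calibrator
#' strain by the delta-delta-Ct method, divided by the target locus's
#' relative chromosome copy number so that a pure dosage effect normalizes
#' to 1.
#'
#' @param ct_target,ct_ref Target- and reference-gene Ct values in the
#'   strain of interest.
#' @param calibrator_ct_target,calibrator_ct_ref The same in the calibrator
#'   (e.g. wild-type haploid) strain.
#' @param copy_ratio Relative copy number of the target locus's chromosome
#'   in the strain (> 0; 1 for euploid).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Fold expression relative to the calibrator.
#' @export
qpcr_expression_fold <- function(ct_target, ct_ref, calibrator_ct_target,
                                 calibrator_ct_ref, copy_ratio = 1,
                                 efficiency = 2) {
  if (any(copy_ratio <= 0)) stop("copy_ratio must be > 0")
  vals <- c(ct_target, ct_ref, calibrator_ct_target, calibrator_ct_ref)
  if (!all(is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target - ct_ref) - (calibrator_ct_target - calibrator_ct_ref)
  efficiency^(-ddct) / copy_ratio
}

#' Spearman correlation between expression change and histone-mark change
#'
#' @param expression Per-gene expression values (e.g. log2 fold change),
#'   named by gene.
#' @param z Per-gene Z-score differences, named by gene; paired with
#'   `expression` on common names (or positionally if unnamed).
#' @return List with `rho`, `p`, `n`, `method`. Exact permutation p for
#'   n <= 9 without ties, t-approximation otherwise.
#' @export
expression_modification_correlation <- function(expression, z) {
  if (!is.null(names(expression)) && !is.null(names(z))) {
    common <- intersect(names(expression), names(z))
    expression <- expression[common]; z <- z[common]
  }
  n <- length(expression)
  if (n < 3 || length(z) != n) stop("need >= 3 paired genes")
  if (length(unique(expression)) == 1 || length(unique(z)) == 1) {
    stop("constant vector: rank correlation undefined")
  }
  ties <- anyDuplicated(expression) > 0 || anyDuplicated(z) > 0
  exact <- n <= 9 && !ties
  ct <- suppressWarnings(
    stats::cor.test(expression, z, method = "spearman", exact = exact)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       method = if (exact) "exact" else "t-approximation")
}
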