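# a small deterministic annotation used across the genomics tests
toy_annotations <- function() {
  gene_annotations(data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chromosome = c("chrI", "chrI", "chrX", "chrX", "chrXII"),
    start = c(2000, 100000, 5000, 300000, 500000),
    end = c(2999, 101999, 6999, 303999, 504999),
    strand = c("+", "-", "+", "+", "-")
  ))
}

test_that("annotation completion derives TSS and length from the strand", {
  ann <- toy_annotations()
  expect_equal(ann$tss, c(2000, 101999, 5000, 300000, 504999))
  expect_equal(ann$length, c(1000, 2000, 2000, 4000, 5000))
  expect_error(gene_annotations(data.frame(
    gene_id = "g", chromosome = "chrI", start = 10, end = 5, strand = "+")))
})

test_that("copy-number normalization divides by the per-sample ratio", {
  ann <- toy_annotations()
  counts <- matrix(c(100, 50, 200, 80, 60,
                     110, 55, 210, 90, 66), ncol = 2,
                   dimnames = list(ann$gene_id, c("wt_1", "dis_1")))
  ratios <- rbind(
    wt_1 = stats::setNames(rep(1, 16), CHROMOSOMES),
    dis_1 = stats::setNames(ifelse(CHROMOSOMES == "chrX", 2, 1),
                            CHROMOSOMES)
  )
  out <- normalize_counts(counts, ann, ratios)
  expect_equal(out[, "wt_1"], counts[, "wt_1"])     # euploid unchanged
  expect_equal(out["gC", "dis_1"], 105)             # 210 / 2
  expect_equal(out["gD", "dis_1"], 45)
  expect_equal(out["gA", "dis_1"], 110)
  expect_error(normalize_counts(counts, ann, ratios[, 1:3]), "copy ratio")
})

test_that("RPKM uses the strict expression gate", {
  ann <- gene_annotations(data.frame(
    gene_id = c("g1", "g2", "g3"), chromosome = "chrI",
    start = c(1, 5001, 10001), end = c(1000, 7000, 12000),
    strand = "+"))
  counts <- matrix(c(10, 0, 25), ncol = 1, dimnames = list(ann$gene_id, "s"))
  r <- rpkm(counts, ann, library_size = c(s = 1e7))
  expect_equal(r$rpkm["g1", "s"], 1.0)       # exactly at the gate
  expect_false(r$expressed["g1", "s"])       # strict >
  expect_equal(r$rpkm["g2", "s"], 0)
  # count 25, length 2000 bp, library 5e6 -> 2.5
  r2 <- rpkm(counts, ann, library_size = c(s = 5e6))
  expect_equal(r2$rpkm["g3", "s"], 2.5)
  expect_error(rpkm(counts, ann, library_size = c(s = 0)), "library")
})

test_that("fold-change categorization applies both gates", {
  ann <- toy_annotations()
  # identical replicate sets in both conditions: everything 'neither'
  m <- matrix(rep(c(100, 50, 200, 80, 60), 4), ncol = 4,
              dimnames = list(ann$gene_id,
                              c("wt_1", "wt_2", "dis_1", "dis_2")))
  res <- de_categorize(m, rep(c("wt", "dis"), each = 2), "dis", "wt")
  expect_true(all(res$category == "neither"))
  expect_true(all(res$p_raw == 1))

  expect_error(de_categorize(m[, c(1, 3, 4)], c("wt", "dis", "dis"),
                             "dis", "wt"), "replicates")
})

test_that("a strong trans effect is detected with high power and the null
           holds the error rate", {
  cfg <- sim_config(seed = 31, trans_fraction = 0, subtel_derepression_fc = 1,
                    nb_dispersion = 0.05)
  ann <- simulate_gene_annotations(cfg, n_genes = 600)
  ratio <- stats::setNames(rep(1, 16), CHROMOSOMES)
  sim <- simulate_counts(cfg, ann, ratio)
  # plant a known 3x trans effect in 60 well-measured genes (base mean at
  # the nominal coverage) of the aneuploid condition
  up_idx <- which(sim$truth$base_mean >= 50 & sim$truth$base_mean <= 500)[1:60]
  aneu_cols <- sim$samples$sample[sim$samples$condition == "aneuploid"]
  counts <- sim$counts
  counts[up_idx, aneu_cols] <- withr::with_seed(99, {
    matrix(stats::rnbinom(60 * length(aneu_cols),
                          mu = 3 * sim$truth$base_mean[up_idx],
                          size = 1 / cfg$nb_dispersion),
           nrow = 60)
  })
  norm <- normalize_counts(counts, ann, sim$copy_ratios)
  res <- de_categorize(norm, sim$samples$condition, "aneuploid", "wt")
  power <- mean(res$category[up_idx] == "up")
  expect_gte(power, 0.95)
  # null genes: fraction called in either direction stays below 1%
  null_rate <- mean(res$category[-up_idx] != "neither")
  expect_lt(null_rate, 0.01)
})

test_that("peaks map to the nearest TSS within 600 bp", {
  ann <- toy_annotations()
  peaks <- data.frame(
    chromosome = c("chrI", "chrI", "chrI", "chrX", "chrM"),
    start = c(1900, 1300, 700, 304500, 5),
    end = c(2100, 1500, 900, 304700, 50),
    score = c(10, 8, 6, 4, 2)
  )
  # peak 1 spans gA's TSS (distance 0); peak 2 ends 500 bp upstream (kept);
  # peak 3 ends 1100 bp upstream (dropped); peak 4 is 501 bp past gD's end,
  # nearest TSS is gD at 304500-300000 -> far, dropped? gD tss=300000,
  # distance = 304500-300000 = 4500 -> dropped; chrM -> skipped with warning
  expect_warning(out <- map_peaks_to_genes(peaks, ann), "skipped")
  expect_equal(out$gene_id, "gA")
  expect_equal(out$score, 10)            # max of 10 and 8
  expect_equal(out$n_peaks, 2L)
  rep <- attr(out, "report")
  expect_equal(rep$n_skipped_chromosome, 1)
  expect_equal(rep$n_dropped_distance, 2)

  # boundary: exactly 600 bp is kept, 601 is not
  p600 <- data.frame(chromosome = "chrI", start = 1000, end = 1400,
                     score = 5)
  expect_equal(map_peaks_to_genes(p600, ann)$gene_id, "gA")
  p601 <- data.frame(chromosome = "chrI", start = 1000, end = 1399,
                     score = 5)
  expect_equal(nrow(map_peaks_to_genes(p601, ann)), 0)

  # nearest of two genes wins
  two <- gene_annotations(data.frame(
    gene_id = c("near", "far"), chromosome = "chrI",
    start = c(5100, 5500), end = c(5900, 6400), strand = c("+", "+")))
  pk <- data.frame(chromosome = "chrI", start = 4900, end = 5000, score = 3)
  expect_equal(map_peaks_to_genes(pk, two)$gene_id, "near")

  # sum mode aggregates multi-peak genes
  expect_warning(out_sum <- map_peaks_to_genes(peaks, ann, combine = "sum"))
  expect_equal(out_sum$score, 18)
})

test_that("peak assignment matches a brute-force all-pairs oracle", {
  cfg <- sim_config(seed = 41)
  ann <- simulate_gene_annotations(cfg, n_genes = 120)
  peaks <- withr::with_seed(8, {
    chr <- sample(unique(ann$chromosome), 200, replace = TRUE)
    pos <- vapply(chr, function(c) {
      sample.int(SACCER3_CHROM_LENGTHS[[c]] - 500, 1)
    }, integer(1))
    data.frame(chromosome = chr, start = pos, end = pos + 400,
               score = stats::runif(200, 1, 50))
  })
  got <- map_peaks_to_genes(peaks, ann, max_distance = 600)
  # oracle: per peak scan every gene
  expected <- list()
  for (i in seq_len(nrow(peaks))) {
    best_gene <- NA; best_d <- Inf
    for (j in seq_len(nrow(ann))) {
      if (ann$chromosome[j] != peaks$chromosome[i]) next
      tss <- ann$tss[j]
      d <- if (tss >= peaks$start[i] && tss <= peaks$end[i]) 0 else
        min(abs(peaks$start[i] - tss), abs(peaks$end[i] - tss))
      if (d < best_d) { best_d <- d; best_gene <- ann$gene_id[j] }
    }
    if (is.finite(best_d) && best_d <= 600) {
      prev <- if (is.null(expected[[best_gene]])) -Inf else
        expected[[best_gene]]
      expected[[best_gene]] <- max(prev, peaks$score[i])
    }
  }
  expect_setequal(got$gene_id, names(expected))
  for (g in got$gene_id) {
    expect_equal(got$score[got$gene_id == g], expected[[g]])
  }
})

test_that("Z-scoring standardizes with the population sd and copy
           normalization cancels dosage", {
  z <- zscore_scores(c(a = 1, b = 2, c = 3))
  expect_equal(unname(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  expect_error(zscore_scores(c(a = 2, b = 2)), "degenerate")

  scores <- withr::with_seed(6, stats::setNames(stats::runif(50, 1, 30),
                                                paste0("g", 1:50)))
  on_gained <- seq_len(20)
  doubled <- scores
  doubled[on_gained] <- doubled[on_gained] * 2
  normalized <- doubled
  normalized[on_gained] <- normalized[on_gained] / 2
  expect_equal(zscore_scores(normalized), zscore_scores(scores))

  expect_equal(unname(delta_z(z, z)), rep(0, 3))
  expect_error(delta_z(c(x = 1), c(y = 1)), "no genes")
})

test_that("subtelomeric flagging uses a strict distance threshold", {
  ann <- gene_annotations(data.frame(
    gene_id = c("left", "mid", "right_in", "right_out"),
    chromosome = "chrX",
    start = c(2000, 300000,
              SACCER3_CHROM_LENGTHS[["chrX"]] - 24999 - 999,
              SACCER3_CHROM_LENGTHS[["chrX"]] - 25001 - 999),
    end = c(2999, 300999,
            SACCER3_CHROM_LENGTHS[["chrX"]] - 24999,
            SACCER3_CHROM_LENGTHS[["chrX"]] - 25001),
    strand = "+"))
  expect_equal(flag_subtelomeric(ann), c(TRUE, FALSE, TRUE, FALSE))
  bad <- ann; bad$end[1] <- SACCER3_CHROM_LENGTHS[["chrX"]] + 1
  expect_error(flag_subtelomeric(bad), "beyond")
})

test_that("Fisher enrichment equals hypergeometric brute force", {
  even <- fisher_category_enrichment(rep(c(TRUE, FALSE), each = 20),
                                     rep(c(TRUE, FALSE), 20))
  expect_equal(even$p, 1)
  expect_equal(even$odds_ratio, 1, tolerance = 1e-6)

  got <- fisher_category_enrichment(
    c(rep(TRUE, 10), rep(FALSE, 10)),
    c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8)))
  expect_equal(got$p, oracle_fisher_p(8, 2, 2, 8), tolerance = 1e-12)

  # random tables with total <= 40
  for (seed in 1:25) {
    tab <- withr::with_seed(seed, {
      n <- sample(8:40, 1)
      flags <- sample(c(TRUE, FALSE), n, replace = TRUE)
      high <- sample(c(TRUE, FALSE), n, replace = TRUE)
      list(flags = flags, high = high)
    })
    t2 <- table(factor(tab$flags, c(TRUE, FALSE)),
                factor(tab$high, c(TRUE, FALSE)))
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    got <- fisher_category_enrichment(tab$flags, tab$high)
    expect_equal(got$p,
                 oracle_fisher_p(t2[1, 1], t2[1, 2], t2[2, 1], t2[2, 2]),
                 tolerance = 1e-12)
  }

  deg <- fisher_category_enrichment(rep(TRUE, 6),
                                    c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("qPCR expression folds normalize dosage away", {
  expect_equal(qpcr_expression_fold(20, 18, 20, 18), 1)
  expect_equal(qpcr_expression_fold(18, 18, 20, 18), 4)   # ddCt = -2
  expect_equal(qpcr_expression_fold(19, 18, 20, 18, copy_ratio = 2), 1)
  expect_error(qpcr_expression_fold(19, 18, 20, 18, copy_ratio = 0))
})

test_that("Spearman correlation handles monotone pairs and matches the
           permutation distribution", {
  mono <- expression_modification_correlation(1:10, (1:10)^2)
  expect_equal(mono$rho, 1)
  rev <- expression_modification_correlation(1:10, -(1:10)^3)
  expect_equal(rev$rho, -1)
  expect_error(expression_modification_correlation(rep(1, 5), 1:5),
               "constant")

  # n = 5 without ties: p agrees with exhaustive enumeration over 5! orders
  x <- c(3.2, 1.5, 4.8, 2.2, 5.9)
  y <- c(1.1, 0.4, 5.0, 2.5, 3.3)
  got <- expression_modification_correlation(x, y)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  rho_all <- apply(perms, 1, function(ord) stats::cor(rank(x), rank(y[ord])))
  p_exact <- mean(abs(rho_all) >= abs(got$rho) - 1e-12)
  expect_equal(got$method, "exact")
  expect_equal(got$p, p_exact, tolerance = 1e-12)
})
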