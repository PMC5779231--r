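#' Simulation configuration
#'
#' One configuration object parameterizes every generator in the package.
#' Defaults reproduce the study conditions the analysis was built around:
#' a triploid-meiosis screen of 3418 spores, 175 imaged cells per strain,
#' a 35% desilenced fraction in the disome X mixture, a 14% G2 fraction,
#' and negative-binomial counts with a 7.5% trans-acting minority.
#'
#' @param seed Master seed; each generator draws from its own substream
#'   derived from it, so generators never perturb each other.
#' @param n_spores Spores per simulated triploid meiosis.
#' @param p_two_copies Per-chromosome probability of receiving 2 copies
#'   (vs 1) in a triploid meiosis.
#' @param n_cells Imaged cells per strain.
#' @param silenced_mean,silenced_sd Natural-scale mean and sd (a.u.) of the
#'   log-normal reporter intensity of silenced cells.
#' @param desilenced_mean,desilenced_sd Same for desilenced cells.
#' @param desilenced_fraction Fraction of desilenced cells in a mixture
#'   population.
#' @param switch_on_rate,switch_off_rate Per-division off-to-on and
#'   on-to-off switching probabilities of the lineage state chain
#'   (placeholder defaults; the study reports no rates).
#' @param zone_probs Length-3 zone probabilities (peripheral, medial,
#'   central), summing to 1.
#' @param nb_mean Median gene-level base mean of the negative-binomial
#'   count model.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param trans_fraction Fraction of genes with trans-acting (non-dosage)
#'   expression changes.
#' @param trans_fc_range Interval the trans fold-change magnitude is drawn
#'   from (log-uniform, direction symmetric).
#' @param subtel_derepression_fc Fold derepression applied to subtelomeric
#'   genes in the aneuploid condition.
#' @param n_replicates Replicates per condition for count and qPCR
#'   generators.
#' @param ct_noise_sd Gaussian noise sd on simulated Ct values (cycles).
#' @param base_ct,ref_ct Baseline target- and reference-locus Ct of the
#'   euploid calibrator.
#' @param g2_fraction_true True G2 fraction of the DNA-content mixture.
#' @param dna_g1_position,dna_g2_position 1N and 2N mode positions (a.u.).
#' @param dna_sd Within-mode sd of DNA content.
#' @param viability Optional list `list(intercept=, slope=)` switching on a
#'   logistic spore-viability penalty in the total deviation from the modal
#'   copy number; `NULL` (default) disables it.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_spores = 3418L,
                       p_two_copies = 0.5,
                       n_cells = 175L,
                       silenced_mean = 100, silenced_sd = 12,
                       desilenced_mean = 500, desilenced_sd = 150,
                       desilenced_fraction = 0.35,
                       switch_on_rate = 0.1, switch_off_rate = 0.1,
                       zone_probs = c(1, 1, 1) / 3,
                       nb_mean = 100, nb_dispersion = 0.05,
                       trans_fraction = 0.075,
                       trans_fc_range = c(1.5, 4),
                       subtel_derepression_fc = 3,
                       n_replicates = 3L,
                       ct_noise_sd = 0.05,
                       base_ct = 20, ref_ct = 18,
                       g2_fraction_true = 0.14,
                       dna_g1_position = 100, dna_g2_position = 200,
                       dna_sd = 10,
                       viability = NULL) {
  cfg <- list(seed = as.integer(seed), n_spores = as.integer(n_spores),
              p_two_copies = p_two_copies, n_cells = as.integer(n_cells),
              silenced_mean = silenced_mean, silenced_sd = silenced_sd,
              desilenced_mean = desilenced_mean,
              desilenced_sd = desilenced_sd,
              desilenced_fraction = desilenced_fraction,
              switch_on_rate = switch_on_rate,
              switch_off_rate = switch_off_rate,
              zone_probs = zone_probs, nb_mean = nb_mean,
              nb_dispersion = nb_dispersion,
              trans_fraction = trans_fraction,
              trans_fc_range = trans_fc_range,
              subtel_derepression_fc = subtel_derepression_fc,
              n_replicates = as.integer(n_replicates),
              ct_noise_sd = ct_noise_sd, base_ct = base_ct, ref_ct = ref_ct,
              g2_fraction_true = g2_fraction_true,
              dna_g1_position = dna_g1_position,
              dna_g2_position = dna_g2_position, dna_sd = dna_sd,
              viability = viability)
  probs <- c(cfg$p_two_copies, cfg$desilenced_fraction, cfg$switch_on_rate,
             cfg$switch_off_rate, cfg$g2_fraction_true)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$zone_probs) - 1) > 1e-9 || any(cfg$zone_probs < 0)) {
    stop("zone_probs must be non-negative and sum to 1")
  }
  if (any(c(cfg$silenced_mean, cfg$silenced_sd, cfg$desilenced_mean,
            cfg$desilenced_sd, cfg$nb_mean, cfg$nb_dispersion) <= 0)) {
    stop("means, sds and dispersions must be > 0")
  }
  structure(cfg, class = "sim_config")
}

# log-normal parameters from a natural-scale mean and sd
lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate spore karyotypes from a triploid meiosis
#'
#' Each of the 16 chromosomes of each spore independently receives 2 copies
#' with probability `p_two_copies` and 1 copy otherwise, modeling the random
#' segregation of three homolog sets. A spore is euploid only when all 16
#' chromosomes drew the same copy number, so the aneuploid fraction follows
#' the closed form `1 - p^16 - (1-p)^16`.
#'
#' @param cfg A [sim_config()].
#' @return List with `karyotypes` (a [karyotype_set()]) and `truth`
#'   (data.frame with per-spore `aneuploid` flag and `n_two_copy`
#'   chromosome count).
#' @export
simulate_triploid_meiosis <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_spores >= 1)
  withr::with_seed(substream_seed(cfg$seed, "meiosis"), {
    copies <- matrix(1L + stats::rbinom(cfg$n_spores * 16L, 1L,
                                        cfg$p_two_copies),
                     nrow = cfg$n_spores, ncol = 16L,
                     dimnames = list(NULL, CHROMOSOMES))
    if (!is.null(cfg$viability)) {
      modal <- apply(copies, 1, function(x) {
        tab <- table(x); as.integer(names(tab)[which.max(tab)])
      })
      dev <- rowSums(abs(copies - modal))
      keep <- stats::runif(cfg$n_spores) <
        stats::plogis(cfg$viability$intercept - cfg$viability$slope * dev)
      copies <- copies[keep, , drop = FALSE]
    }
    ids <- sprintf("spore_%05d", seq_len(nrow(copies)))
    ks <- lapply(seq_len(nrow(copies)), function(i) {
      karyotype(ids[i], copies[i, ])
    })
    n_two <- rowSums(copies == 2L)
    truth <- data.frame(strain_id = ids, n_two_copy = n_two,
                        aneuploid = n_two > 0L & n_two < 16L)
    list(karyotypes = karyotype_set(ks, label = "triploid_meiosis"),
         truth = truth)
  })
}

#' Simulate a per-cell fluorescence population
#'
#' Silenced and desilenced cells draw their mean reporter intensity from
#' log-normal distributions around `silenced_mean` and `desilenced_mean`;
#' a `"desilenced_mixture"` population is desilenced with probability
#' `desilenced_fraction`, a `"euploid"` population never is.
#'
#' @param cfg A [sim_config()].
#' @param strain_kind `"euploid"` or `"desilenced_mixture"`.
#' @param strain_id Strain identifier for the emitted table.
#' @return List with `cells` (data.frame `strain_id, cell_id, channel,
#'   mean_intensity, sd_intensity, n_pixels`) and `truth` (per-cell logical
#'   `desilenced`).
#' @export
simulate_cell_population <- function(cfg,
                                     strain_kind = c("euploid",
                                                     "desilenced_mixture"),
                                     strain_id = strain_kind) {
  strain_kind <- match.arg(strain_kind)
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$desilenced_mean <= cfg$silenced_mean) {
    warning("desilenced_mean <= silenced_mean: states are not separable")
  }
  withr::with_seed(substream_seed(cfg$seed, "cells"), {
    n <- cfg$n_cells
    state <- if (strain_kind == "euploid") rep(FALSE, n) else
      stats::runif(n) < cfg$desilenced_fraction
    ps <- lnorm_params(cfg$silenced_mean, cfg$silenced_sd)
    pd <- lnorm_params(cfg$desilenced_mean, cfg$desilenced_sd)
    m <- ifelse(state,
                stats::rlnorm(n, pd["meanlog"], pd["sdlog"]),
                stats::rlnorm(n, ps["meanlog"], ps["sdlog"]))
    cells <- data.frame(
      strain_id = strain_id,
      cell_id = sprintf("%s_cell_%04d", strain_id, seq_len(n)),
      channel = "YFP",
      mean_intensity = m,
      sd_intensity = m * stats::runif(n, 0.25, 0.45),
      n_pixels = sample(800:1200, n, replace = TRUE)
    )
    list(cells = cells,
         truth = data.frame(cell_id = cells$cell_id, desilenced = state))
  })
}

#' Simulate a fluorescence lineage trace
#'
#' A two-state Markov chain over cell divisions: starting silenced (off),
#' the lineage switches off-to-on with `switch_on_rate` and on-to-off with
#' `switch_off_rate` per division; intensity at each timepoint (90-minute
#' divisions) is drawn from the current state's distribution. Rates (0, 0)
#' model a stable haploid lineage that never switches.
#'
#' @param cfg A [sim_config()].
#' @param n_divisions Number of divisions after the initial timepoint.
#' @param lineage_id Identifier for the emitted trace.
#' @param seed_offset Optional integer mixed into the lineage substream so
#'   many independent lineages can be drawn from one configuration.
#' @return List with `trace` (data.frame `lineage_id, time_min, intensity`)
#'   and `truth` (logical state per timepoint).
#' @export
simulate_lineage <- function(cfg, n_divisions, lineage_id = "lineage_1",
                             seed_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"), n_divisions >= 1)
  seed <- substream_seed(cfg$seed, "lineage") + as.integer(seed_offset)
  withr::with_seed(seed, {
    n <- n_divisions + 1L
    state <- logical(n)   # start silenced
    for (i in seq_len(n_divisions)) {
      state[i + 1] <- if (state[i]) {
        stats::runif(1) >= cfg$switch_off_rate
      } else {
        stats::runif(1) < cfg$switch_on_rate
      }
    }
    ps <- lnorm_params(cfg$silenced_mean, cfg$silenced_sd)
    pd <- lnorm_params(cfg$desilenced_mean, cfg$desilenced_sd)
    intensity <- ifelse(state,
                        stats::rlnorm(n, pd["meanlog"], pd["sdlog"]),
                        stats::rlnorm(n, ps["meanlog"], ps["sdlog"]))
    trace <- data.frame(lineage_id = lineage_id,
                        time_min = 90 * (seq_len(n) - 1L),
                        intensity = intensity)
    list(trace = trace, truth = state)
  })
}

#' Simulate tagged-locus positions in nuclear cross-sections
#'
#' Per cell, a zone is drawn from `zone_probs` and the locus is placed
#' area-uniformly within that zone's annulus of a circular nuclear
#' cross-section; nuclear radius and center vary per cell. Uniform
#' `zone_probs` reproduce the uniform (33% per zone) null.
#'
#' @param cfg A [sim_config()].
#' @param n_cells Number of cells (default `cfg$n_cells`).
#' @return List with `loci` (data.frame
#'   `cell_id, center_x, center_y, radius, locus_x, locus_y`) and `truth`
#'   (integer zone per cell).
#' @export
simulate_locus_positions <- function(cfg, n_cells = cfg$n_cells) {
  stopifnot(inherits(cfg, "sim_config"), n_cells >= 1)
  withr::with_seed(substream_seed(cfg$seed, "loci"), {
    zone <- sample(1:3, n_cells, replace = TRUE, prob = cfg$zone_probs)
    b <- c(0, zone_boundaries("area"), 1)    # relative radii 0..1
    lo <- c(b[3], b[2], b[1])[zone]          # zone 1 is the outer annulus
    hi <- c(b[4], b[3], b[2])[zone]
    rho <- sqrt(lo^2 + stats::runif(n_cells) * (hi^2 - lo^2))
    theta <- stats::runif(n_cells, 0, 2 * pi)
    radius <- stats::runif(n_cells, 0.8, 1.2)      # microns
    center_x <- stats::runif(n_cells, 0, 50)
    center_y <- stats::runif(n_cells, 0, 50)
    loci <- data.frame(
      cell_id = sprintf("cell_%05d", seq_len(n_cells)),
      center_x = center_x, center_y = center_y, radius = radius,
      locus_x = center_x + radius * rho * cos(theta),
      locus_y = center_y + radius * rho * sin(theta)
    )
    list(loci = loci, truth = zone)
  })
}

#' Lay out a synthetic yeast gene annotation
#'
#' Distributes genes along the sixteen sacCer3 chromosomes proportionally to
#' chromosome length, with log-normal gene lengths and alternating strands —
#' a synthetic stand-in for a genome annotation, adequate for dosage,
#' RPKM, subtelomere and peak-assignment arithmetic.
#'
#' @param cfg A [sim_config()].
#' @param n_genes Total genes to place (default 2000).
#' @return Annotation table from [gene_annotations()].
#' @export
simulate_gene_annotations <- function(cfg, n_genes = 2000L) {
  stopifnot(inherits(cfg, "sim_config"), n_genes >= 16)
  withr::with_seed(substream_seed(cfg$seed, "annotations"), {
    lens <- SACCER3_CHROM_LENGTHS
    per_chrom <- pmax(round(n_genes * lens / sum(lens)), 1L)
    rows <- lapply(names(per_chrom), function(chr) {
      n <- per_chrom[[chr]]
      slot <- lens[[chr]] / n
      glen <- pmin(round(stats::rlnorm(n, log(1200), 0.45)),
                   floor(slot * 0.8))
      glen <- pmin(pmax(glen, 300L), floor(slot) - 2L)
      start <- floor((seq_len(n) - 1) * slot) +
        floor(stats::runif(n, 1, pmax(2, slot - glen)))
      data.frame(
        gene_id = sprintf("%s_g%04d", sub("^chr", "", chr), seq_len(n)),
        chromosome = chr, start = as.integer(start),
        end = as.integer(start + glen - 1L),
        strand = rep_len(c("+", "-"), n)
      )
    })
    gene_annotations(do.call(rbind, rows))
  })
}

#' Simulate a gene-level count table with dosage and trans effects
#'
#' Negative-binomial counts for a wild-type (euploid) and an aneuploid
#' condition with `n_replicates` each. The per-gene aneuploid mean is the
#' base mean multiplied by the chromosome copy ratio (the dosage effect), a
#' trans-acting fold change for a `trans_fraction` minority of genes off the
#' gained chromosomes (log-uniform magnitude, symmetric direction), and
#' `subtel_derepression_fc` for subtelomeric genes.
#'
#' @param cfg A [sim_config()].
#' @param annotations Annotation table (e.g. from
#'   [simulate_gene_annotations()]).
#' @param copy_ratio Named chromosome copy-ratio vector for the aneuploid
#'   strain (see [copy_profile()]).
#' @param subtel_threshold Subtelomere distance used for derepression
#'   flagging (bp).
#' @return List with `counts` (genes x samples integer matrix), `samples`
#'   (data.frame `sample, condition`), `copy_ratios` (samples x chromosome
#'   matrix for [normalize_counts()]), and `truth` (per-gene chromosome,
#'   base mean, dosage ratio, trans and subtelomeric fold changes, and the
#'   total expected fold change).
#' @export
simulate_counts <- function(cfg, annotations, copy_ratio,
                            subtel_threshold = 25000) {
  stopifnot(inherits(cfg, "sim_config"))
  missing_chr <- setdiff(unique(annotations$chromosome), names(copy_ratio))
  if (length(missing_chr) > 0) {
    stop("copy_ratio missing chromosomes: ",
         paste(missing_chr, collapse = ", "))
  }
  withr::with_seed(substream_seed(cfg$seed, "counts"), {
    g <- nrow(annotations)
    base_mean <- stats::rlnorm(g, log(cfg$nb_mean), 1)
    ratio <- as.numeric(copy_ratio[annotations$chromosome])
    subtel <- flag_subtelomeric(annotations, threshold = subtel_threshold)
    eligible <- which(ratio == 1)   # trans effects off the gained chromosomes
    n_trans <- round(cfg$trans_fraction * g)
    trans_idx <- sample(eligible, min(n_trans, length(eligible)))
    trans_fc <- rep(1, g)
    mag <- exp(stats::runif(length(trans_idx),
                            log(cfg$trans_fc_range[1]),
                            log(cfg$trans_fc_range[2])))
    dir <- sample(c(-1, 1), length(trans_idx), replace = TRUE)
    trans_fc[trans_idx] <- mag^dir
    subtel_fc <- ifelse(subtel, cfg$subtel_derepression_fc, 1)

    n_rep <- cfg$n_replicates
    samples <- data.frame(
      sample = c(sprintf("wt_%d", seq_len(n_rep)),
                 sprintf("aneuploid_%d", seq_len(n_rep))),
      condition = rep(c("wt", "aneuploid"), each = n_rep)
    )
    size <- 1 / cfg$nb_dispersion
    counts <- matrix(0L, nrow = g, ncol = nrow(samples),
                     dimnames = list(annotations$gene_id, samples$sample))
    mu_wt <- base_mean
    mu_an <- base_mean * ratio * trans_fc * subtel_fc
    for (j in seq_len(nrow(samples))) {
      mu <- if (samples$condition[j] == "wt") mu_wt else mu_an
      counts[, j] <- stats::rnbinom(g, mu = mu, size = size)
    }
    copy_ratios <- rbind(
      matrix(1, nrow = n_rep, ncol = 16,
             dimnames = list(samples$sample[seq_len(n_rep)], CHROMOSOMES)),
      matrix(copy_ratio[CHROMOSOMES], nrow = n_rep, ncol = 16, byrow = TRUE,
             dimnames = list(samples$sample[n_rep + seq_len(n_rep)],
                             CHROMOSOMES))
    )
    truth <- data.frame(gene_id = annotations$gene_id,
                        chromosome = annotations$chromosome,
                        base_mean = base_mean, dosage_ratio = ratio,
                        trans_fc = trans_fc, subtel = subtel,
                        subtel_fc = subtel_fc,
                        expected_fc = ratio * trans_fc * subtel_fc)
    list(counts = counts, samples = samples, copy_ratios = copy_ratios,
         truth = truth)
  })
}

#' Simulate qPCR Ct records for a known karyotype
#'
#' Target-locus Ct drops by one cycle per copy-number doubling:
#' `ct_target = base_ct - log2(copies / basal) + noise`; the reference locus
#' and the euploid calibrator are consistent with `base_ct` and `ref_ct`,
#' so noise-free records give `ddCt = -log2(copies / basal)` exactly.
#'
#' @param cfg A [sim_config()].
#' @param k The true [karyotype()].
#' @param seed_offset Optional integer mixed into the qPCR substream for
#'   simulating many strains from one configuration.
#' @return data.frame of Ct records (one row per chromosome x replicate)
#'   for [call_copy_number_qpcr()].
#' @export
simulate_qpcr <- function(cfg, k, seed_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(k, "karyotype"))
  basal <- basal_ploidy(k)
  seed <- substream_seed(cfg$seed, "qpcr") + as.integer(seed_offset)
  withr::with_seed(seed, {
    n_rep <- cfg$n_replicates
    rows <- expand.grid(chromosome = CHROMOSOMES,
                        replicate = seq_len(n_rep),
                        stringsAsFactors = FALSE)
    copies <- k$copies[rows$chromosome]
    n <- nrow(rows)
    data.frame(
      strain_id = k$strain_id,
      chromosome = rows$chromosome,
      replicate = rows$replicate,
      ct_target = cfg$base_ct - log2(copies / basal) +
        stats::rnorm(n, 0, cfg$ct_noise_sd),
      ct_reference = cfg$ref_ct + stats::rnorm(n, 0, cfg$ct_noise_sd),
      calibrator_delta_ct = cfg$base_ct - cfg$ref_ct
    )
  })
}

#' Simulate a DNA-content histogram sample
#'
#' A two-Gaussian mixture at the 1N and 2N modes with G2 weight
#' `g2_fraction_true`.
#'
#' @param cfg A [sim_config()].
#' @param n_cells Number of cells (default `cfg$n_cells`).
#' @return List with `values` (per-cell DNA content), `g1_position`,
#'   `g2_position`, and `truth` (logical G2 state per cell).
#' @export
simulate_dna_content <- function(cfg, n_cells = cfg$n_cells) {
  stopifnot(inherits(cfg, "sim_config"), n_cells >= 1)
  if (cfg$dna_g2_position - cfg$dna_g1_position < 3 * cfg$dna_sd * sqrt(2)) {
    warning("1N and 2N modes overlap; G2 gating will be biased")
  }
  withr::with_seed(substream_seed(cfg$seed, "dna"), {
    g2 <- stats::runif(n_cells) < cfg$g2_fraction_true
    values <- stats::rnorm(n_cells,
                           ifelse(g2, cfg$dna_g2_position,
                                  cfg$dna_g1_position),
                           cfg$dna_sd)
    list(values = values, g1_position = cfg$dna_g1_position,
         g2_position = cfg$dna_g2_position, truth = g2)
  })
}
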