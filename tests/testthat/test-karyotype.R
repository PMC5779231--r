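test_that("basal ploidy is the modal copy number and ties are refused", {
  expect_equal(basal_ploidy(karyotype("hap", rep(1L, 16))), 1)
  # haploid base with gains of III (to 3 copies) and X
  k <- karyotype("g3x", c(chrIII = 3, chrX = 2), base = 1)
  expect_equal(basal_ploidy(k), 1)
  expect_equal(basal_ploidy(karyotype("dip", rep(2L, 16))), 2)
  # eight chromosomes at 2, eight at 3: tie, carries both candidates
  tied <- karyotype("tie", c(rep(2L, 8), rep(3L, 8)))
  err <- tryCatch(basal_ploidy(tied), error = identity)
  expect_s3_class(err, "basal_ploidy_tie")
  expect_setequal(err$candidates, c(2, 3))
})

test_that("basal ploidy is invariant under chromosome relabeling", {
  copies <- c(3L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(16))
    expect_equal(basal_ploidy(karyotype("p", copies[perm])), 1)
  }
})

test_that("aneuploid chromosomes are the signed deviations from basal", {
  expect_length(aneuploid_chromosomes(karyotype("dip", rep(2L, 16))), 0)
  dev <- aneuploid_chromosomes(karyotype("a", c(chrIII = 3, chrX = 2),
                                         base = 1))
  expect_equal(dev, c(chrIII = 2L, chrX = 1L))
  dev2 <- aneuploid_chromosomes(
    karyotype("b", c(chrI = 2, chrX = 2, chrXII = 2, chrXIII = 2), base = 1))
  expect_equal(dev2, c(chrI = 1L, chrX = 1L, chrXII = 1L, chrXIII = 1L))
  # empty deviation set iff all copies equal
  for (seed in 1:10) {
    copies <- withr::with_seed(seed, {
      base <- sample(1:3, 1)
      x <- rep(base, 16)
      if (seed %% 2 == 0) x[sample(16, sample(1:5, 1))] <- base + 1L
      x
    })
    expect_equal(length(aneuploid_chromosomes(karyotype("k", copies))) == 0,
                 all(copies == copies[1]))
  }
})

test_that("qPCR copy calling inverts the delta-delta-Ct model", {
  recs <- data.frame(strain_id = "s", chromosome = CHROMOSOMES,
                     ct_target = 20, ct_reference = 18,
                     calibrator_delta_ct = 2)
  expect_equal(unname(call_copy_number_qpcr(recs, basal = 1)$copies),
               rep(1L, 16))

  # one-cycle drop on chromosome X doubles its called copy number
  recs2 <- recs
  recs2$ct_target[recs2$chromosome == "chrX"] <- 19
  k2 <- call_copy_number_qpcr(recs2, basal = 1)
  expect_equal(unname(k2$copies[CHROMOSOMES == "chrX"]), 2L)
  expect_equal(unname(k2$copies[CHROMOSOMES != "chrX"]), rep(1L, 15))

  # ddCt = -0.585 on a diploid base: 2^0.585 = 1.500 -> 3 copies
  expect_equal(2^0.585, 1.5, tolerance = 1e-3)
  recs3 <- recs
  recs3$ct_target[recs3$chromosome == "chrIII"] <- 20 - 0.585
  k3 <- call_copy_number_qpcr(recs3, basal = 2)
  expect_equal(unname(k3$copies[CHROMOSOMES == "chrIII"]), 3L)
  expect_false(attr(k3, "ambiguous")[["chrIII"]])

  # missing chromosomes are reported by name
  expect_error(call_copy_number_qpcr(recs[-(1:2), ], basal = 1),
               "chrI, chrII")

  # far-from-integer calls are flagged ambiguous
  recs4 <- recs
  recs4$ct_target[recs4$chromosome == "chrV"] <- 20 - 0.55  # rq ~ 1.46
  k4 <- call_copy_number_qpcr(recs4, basal = 1)
  expect_true(attr(k4, "ambiguous")[["chrV"]])
})

test_that("gain counts tally aneuploid strains per chromosome", {
  eu <- karyotype_set(lapply(1:3, function(i) {
    karyotype(paste0("eu", i), rep(1L, 16))
  }), "euploid")
  expect_equal(unname(gain_counts(eu)), rep(0L, 16))

  # the two segregant-parent karyotypes: gains of III,III,X and I,X,XII,XIII
  s <- karyotype_set(list(
    karyotype("gain_III_III_X", c(chrIII = 3, chrX = 2), base = 1),
    karyotype("gain_I_X_XII_XIII",
              c(chrI = 2, chrX = 2, chrXII = 2, chrXIII = 2), base = 1)
  ), "parents")
  gc <- gain_counts(s)
  expect_equal(gc[["chrX"]], 2L)
  expect_equal(gc[["chrIII"]], 1L)
  expect_equal(gc[["chrI"]], 1L)
  expect_equal(gc[["chrXII"]], 1L)
  expect_equal(gc[["chrXIII"]], 1L)
  expect_equal(sum(gc), 6L)

  # losses count by default but not in gains-only mode
  s2 <- karyotype_set(list(karyotype("loss", c(chrV = 1), base = 2)), "l")
  expect_equal(gain_counts(s2)[["chrV"]], 1L)
  expect_equal(gain_counts(s2, gains_only = TRUE)[["chrV"]], 0L)

  expect_error(karyotype_set(list(karyotype("dup", rep(1L, 16)),
                                  karyotype("dup", rep(2L, 16)))),
               "duplicate")
  expect_error(gain_counts(karyotype_set(list(), "empty")), "empty")
})

test_that("enrichment test matches the brute-force binomial tail", {
  # case: 5 of 8 strains aneuploid for chrX; reference: 10 of 38
  case_ind <- matrix(FALSE, 8, 16, dimnames = list(NULL, CHROMOSOMES))
  case_ind[1:5, "chrX"] <- TRUE
  ref_ind <- matrix(FALSE, 38, 16, dimnames = list(NULL, CHROMOSOMES))
  ref_ind[1:10, "chrX"] <- TRUE
  res <- enrichment_test(karyotype_set_from_indicators(case_ind, "case"),
                         karyotype_set_from_indicators(ref_ind, "ref"))
  row <- res[res$chromosome == "chrX", ]
  expect_equal(row$case_count, 5)
  expect_equal(row$reference_freq, 10 / 38)
  expect_equal(row$p_raw, oracle_binom_upper(5, 8, 10 / 38),
               tolerance = 1e-12)

  # zero case count gives upper-tail p of exactly 1
  expect_equal(res$p_raw[res$chromosome == "chrI"], 1)
  # never-aneuploid reference chromosomes get the half-count pseudofrequency
  expect_equal(res$reference_freq[res$chromosome == "chrI"], 0.5 / 38)
  # BH adjustment never decreases a p-value
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))

  # saturated case with reference frequency 1
  sat_case <- matrix(FALSE, 4, 16, dimnames = list(NULL, CHROMOSOMES))
  sat_case[, "chrII"] <- TRUE
  sat_ref <- matrix(FALSE, 6, 16, dimnames = list(NULL, CHROMOSOMES))
  sat_ref[, "chrII"] <- TRUE
  res_sat <- enrichment_test(karyotype_set_from_indicators(sat_case, "c"),
                             karyotype_set_from_indicators(sat_ref, "r"))
  expect_equal(res_sat$p_raw[res_sat$chromosome == "chrII"], 1)
})

test_that("exact binomial p agrees with tail summation on random instances", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n_case <- sample(2:12, 1)
      n_ref <- sample(10:40, 1)
      case_ind <- matrix(stats::runif(n_case * 16) < 0.3, n_case, 16,
                         dimnames = list(NULL, CHROMOSOMES))
      ref_ind <- matrix(stats::runif(n_ref * 16) < 0.3, n_ref, 16,
                        dimnames = list(NULL, CHROMOSOMES))
      res <- enrichment_test(karyotype_set_from_indicators(case_ind, "c"),
                             karyotype_set_from_indicators(ref_ind, "r"))
      freq <- res$reference_freq
      for (j in seq_len(16)) {
        expect_equal(res$p_raw[j],
                     oracle_binom_upper(res$case_count[j], n_case, freq[j]),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("screen rate reports percent with an exact interval", {
  sr <- screen_rate(98, 3418)
  expect_equal(sr$percent, 100 * 98 / 3418)
  expect_equal(round(sr$percent), 3)
  expect_equal(screen_rate(0, 100)$percent, 0)
  sr2 <- screen_rate(50, 100)
  cp <- oracle_cp_interval(50, 100)
  expect_equal(sr2$ci_lower, 100 * cp[1], tolerance = 1e-7)
  expect_equal(sr2$ci_upper, 100 * cp[2], tolerance = 1e-7)
  expect_error(screen_rate(1, 0))
  expect_error(screen_rate(5, 4))
})

test_that("karyotype CSV round-trips through the table form", {
  s <- karyotype_set(list(
    karyotype("a", c(chrIII = 3, chrX = 2), base = 1, phenotype = TRUE),
    karyotype("b", rep(2L, 16), phenotype = FALSE),
    karyotype("c", rep(1L, 16))
  ), "demo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_karyotypes(s, path)
  s2 <- read_karyotypes(path, label = "demo")
  expect_equal(as.data.frame(s2), as.data.frame(s))
  expect_true(s2[[1]]$phenotype)
  expect_false(s2[[2]]$phenotype)
  expect_true(is.na(s2[[3]]$phenotype))
})
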