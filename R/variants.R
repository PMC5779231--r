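#' Read variant records from a VCF file
#'
#' Reads the fixed columns of a VCF (v4.x) into the flat record form used by
#' [filter_background_variants()]. FILTER-field flags `repetitive`,
#' `homopolymer` and `low_qual` are carried through.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param strain_id Strain the file belongs to.
#' @return data.frame with columns `strain_id`, `chromosome`, `position`,
#'   `ref`, `alt`, `filter`.
#' @export
read_variants_vcf <- function(path, strain_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  data.frame(strain_id = strain_id,
             chromosome = fx$CHROM,
             position = as.integer(fx$POS),
             ref = fx$REF,
             alt = fx$ALT,
             filter = ifelse(is.na(fx$FILTER), "", fx$FILTER),
             stringsAsFactors = FALSE)
}

#' Remove background variants shared with the parental euploid strains
#'
#' A variant (chromosome, position, ref, alt) called in an aneuploid strain
#' is discarded when (i) the identical variant occurs in every sequenced
#' strain, or (ii) it occurs in any parental strain — both indicate a
#' mutation already present in the euploid background rather than one that
#' arose with the aneuploidy. Variants whose `filter` field carries any of
#' the declared quality flags (`repetitive`, `homopolymer`, `low_qual`) are
#' also discarded. Removal reasons are counted with the precedence
#' shared-by-all > parental > quality flag.
#'
#' @param variants data.frame with columns `strain_id`, `chromosome`,
#'   `position`, `ref`, `alt` and optionally `filter` (semicolon-separated
#'   flags; empty, `"."` or `"PASS"` means unflagged).
#' @param parental_ids Character vector of parental (euploid) strain ids;
#'   at least one must occur in `variants$strain_id`'s universe of sequenced
#'   strains.
#' @return List with `retained` (the surviving aneuploid-strain records) and
#'   `removed_counts` (named integer vector: `shared_all`, `parental`,
#'   `repetitive`, `homopolymer`, `low_qual`).
#' @export
filter_background_variants <- function(variants, parental_ids) {
  stopifnot(is.data.frame(variants),
            all(c("strain_id", "chromosome", "position", "ref",
                  "alt") %in% names(variants)))
  if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
  if (length(parental_ids) == 0 ||
      !any(parental_ids %in% variants$strain_id)) {
    stop("no parental strain present among the sequenced strains")
  }
  if (!"filter" %in% names(variants)) variants$filter <- ""
  key <- paste(variants$chromosome, variants$position, variants$ref,
               variants$alt, sep = ":")
  strains <- unique(variants$strain_id)
  n_strains_with <- tapply(variants$strain_id, key,
                           function(s) length(unique(s)))
  shared_all_keys <- names(n_strains_with)[n_strains_with == length(strains)]
  parental_keys <- unique(key[variants$strain_id %in% parental_ids])

  aneuploid <- !(variants$strain_id %in% parental_ids)
  flag_of <- function(flag) {
    vapply(strsplit(variants$filter, ";", fixed = TRUE),
           function(f) flag %in% f, logical(1))
  }
  is_shared <- key %in% shared_all_keys
  is_parental <- key %in% parental_keys
  is_rep <- flag_of("repetitive")
  is_homo <- flag_of("homopolymer")
  is_lowq <- flag_of("low_qual")

  reason <- rep(NA_character_, nrow(variants))
  reason[is_lowq] <- "low_qual"
  reason[is_homo] <- "homopolymer"
  reason[is_rep] <- "repetitive"
  reason[is_parental] <- "parental"
  reason[is_shared] <- "shared_all"

  drop <- aneuploid & !is.na(reason)
  retained <- variants[aneuploid & is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  removed <- table(factor(reason[drop],
                          levels = c("shared_all", "parental", "repetitive",
                                     "homopolymer", "low_qual")))
  list(retained = retained,
       removed_counts = stats::setNames(as.integer(removed), names(removed)))
}
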