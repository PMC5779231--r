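#' The sixteen budding-yeast chromosomes
#'
#' Canonical chromosome labels used throughout the package, in karyotype
#' order (`chrI` < `chrII` < ... < `chrXVI`).
#'
#' @format Character vector of length 16.
#' @export
CHROMOSOMES <- paste0("chr", as.roman(1:16))

#' sacCer3 chromosome lengths
#'
#' Lengths in base pairs of the sixteen nuclear chromosomes of the
#' S. cerevisiae sacCer3 reference assembly, named by [CHROMOSOMES].
#' Used as the default for subtelomere flagging and for laying out
#' synthetic gene annotations.
#'
#' @format Named integer vector of length 16.
#' @export
SACCER3_CHROM_LENGTHS <- c(
  chrI    = 230218L,  chrII  = 813184L,  chrIII  = 316620L,
  chrIV   = 1531933L, chrV   = 576874L,  chrVI   = 270161L,
  chrVII  = 1090940L, chrVIII = 562643L, chrIX   = 439888L,
  chrX    = 745751L,  chrXI  = 666816L,  chrXII  = 1078177L,
  chrXIII = 924431L,  chrXIV = 784333L,  chrXV   = 1091291L,
  chrXVI  = 948066L
)

# Normalize user-supplied chromosome labels ("X", "chrX", "chr10", "10")
# to the canonical "chrX" form; errors on anything unrecognized.
normalize_chromosome <- function(x) {
  x <- as.character(x)
  bare <- sub("^chr", "", x)
  roman <- toupper(bare)
  # arabic numerals accepted too
  num <- suppressWarnings(as.integer(bare))
  roman[!is.na(num)] <- as.character(as.roman(num[!is.na(num)]))
  out <- paste0("chr", roman)
  bad <- !(out %in% CHROMOSOMES)
  if (any(bad)) {
    stop("unrecognized chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  factor(out, levels = CHROMOSOMES)
}
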