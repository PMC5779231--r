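#' Read or write a karyotype table
#'
#' Karyotype tables are CSV with header
#' `strain_id,chrI,...,chrXVI,phenotype`; copies are integers, phenotype is
#' 0/1/NA.
#'
#' @param path File path.
#' @param label Set label attached on read.
#' @return [read_karyotypes()] returns a [karyotype_set()].
#' @export
read_karyotypes <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_karyotype_set(df, label = label)
}

#' @rdname read_karyotypes
#' @param s A [karyotype_set()] to write.
#' @export
write_karyotypes <- function(s, path) {
  utils::write.csv(as.data.frame(s), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' CSV with columns
#' `strain_id,chromosome,replicate,ct_target,ct_reference,calibrator_delta_ct`.
#'
#' @param path File path.
#' @return data.frame suitable for [call_copy_number_qpcr()].
#' @export
read_qpcr <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read a per-cell fluorescence table
#'
#' CSV with columns
#' `strain_id,cell_id,channel,mean_intensity,sd_intensity,n_pixels`.
#'
#' @param path File path.
#' @return data.frame of per-cell measurements.
#' @export
read_cells <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read a tagged-locus position table
#'
#' CSV with columns `cell_id,center_x,center_y,radius,locus_x,locus_y`.
#'
#' @param path File path.
#' @return data.frame suitable for [classify_zones()].
#' @export
read_loci <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3 files are filtered to `gene` features and read with their 1-based
#' inclusive coordinates; BED files (0-based half-open) are converted to the
#' same internal convention on read.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format Override the extension-based format guess.
#' @return Annotation table from [gene_annotations()].
#' @export
read_gene_annotations <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  } else {
    ids <- gr$name
  }
  gene_annotations(data.frame(
    gene_id = as.character(ids),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    stringsAsFactors = FALSE
  ))
}

#' Read ChIP peak calls from a scored BED file
#'
#' The BED name field carries strain and mark as `strain|mark`; the score
#' column is the peak score (-log10 q-value). Coordinates are converted to
#' 1-based inclusive.
#'
#' @param path Path to the BED file.
#' @return data.frame with columns `chromosome`, `start`, `end`, `score`,
#'   `strain_id`, `mark`.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- strsplit(as.character(gr$name), "|", fixed = TRUE)
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score),
    strain_id = vapply(nm, `[`, character(1), 1),
    mark = vapply(nm, function(x) if (length(x) > 1) x[2] else NA_character_,
                  character(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-by-sample count table
#'
#' TSV with gene ids in the first column and one column per sample.
#'
#' @param path File path.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a chromosome-length table
#'
#' TSV with columns `chromosome` and `length`.
#'
#' @param path File path.
#' @return Named integer vector.
#' @export
read_chrom_lengths <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stats::setNames(as.integer(df$length),
                  as.character(normalize_chromosome(df$chromosome)))
}

#' Write an enrichment-result table
#'
#' One row per chromosome with counts, frequencies and raw/adjusted
#' p-values, as produced by [enrichment_test()].
#'
#' @param results data.frame from [enrichment_test()].
#' @param path Output TSV path.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
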