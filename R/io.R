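#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file path.
#' @return data.frame with `id`, `seq`, `qual` columns.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Write a genome to FASTA
#' @param genome Named `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write the simulator truth table as TSV and BED
#'
#' The BED carries `chrom`, `start`, `end`, `site_id`, a motif flag as
#' score, and `.` strand; the TSV carries every truth column.
#'
#' @param truth Truth table from [plant_sites()].
#' @param tsv_path,bed_path Output paths (either may be `NULL` to skip).
#' @export
write_truth <- function(truth, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(truth, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(truth$chrom, truth$start, truth$end, truth$site_id,
                      as.integer(truth$has_motif), ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(truth)
}

#' Write deduplicated tags as 6-column BED
#'
#' Columns: chrom, stop5, stop5+1, barcode, mapq, strand.
#' @param tags Tag data.frame.
#' @param path Output path.
#' @export
write_tags_bed <- function(tags, path) {
  bed <- data.frame(tags$chrom, tags$stop5, tags$stop5 + 1L, tags$barcode,
                    tags$mapq, tags$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read tags from 6-column BED written by [write_tags_bed()]
#' @param path BED path.
#' @return Tag data.frame (`chrom`, `strand`, `stop5`, `barcode`, `mapq`).
#' @export
read_tags_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "barcode",
                                       "mapq", "strand"))
  data.frame(chrom = x$chrom, strand = x$strand, stop5 = x$start,
             barcode = x$barcode, mapq = x$mapq, stringsAsFactors = FALSE)
}

#' Write peaks in narrowPeak (BED6+4) format
#'
#' Columns: chrom, start, end, name, score, strand ".", fold enrichment,
#' -log10 p, -log10 q, summit offset from start.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  if (nrow(peaks) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  np <- data.frame(
    peaks$chrom, peaks$start, peaks$end, peaks$name,
    pmin(1000L, as.integer(round(-10 * log10(pmax(peaks$qvalue, 1e-100))))),
    ".",
    signif(peaks$fold_enrichment, 5),
    signif(-log10(pmax(peaks$pvalue, 1e-300)), 5),
    signif(-log10(pmax(peaks$qvalue, 1e-300)), 5),
    peaks$summit - peaks$start
  )
  utils::write.table(np, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from a narrowPeak file
#' @param path narrowPeak path.
#' @return Peak data.frame compatible with the rest of the pipeline.
#' @export
read_narrowpeak <- function(path) {
  if (file.size(path) == 0) return(.empty_peaks())
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand", "fold_enrichment",
                                       "neglog10p", "neglog10q", "peak"))
  data.frame(chrom = x$chrom, start = x$start, end = x$end, name = x$name,
             summit = x$start + x$peak, pvalue = 10^(-x$neglog10p),
             qvalue = 10^(-x$neglog10q), fold_enrichment = x$fold_enrichment,
             stringsAsFactors = FALSE)
}

#' Read gene models from 6-column BED
#' @param path BED path (chrom, start, end, gene_id, score, strand).
#' @return Gene-model data.frame.
#' @export
read_gene_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "gene_id",
                                       "score", "strand"))
  data.frame(gene_id = x$gene_id, chrom = x$chrom, start = x$start,
             end = x$end, strand = x$strand, stringsAsFactors = FALSE)
}

#' Write gene models as 6-column BED
#' @param genes Gene-model data.frame.
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# convert half-open 0-based peak/region data.frames to GRanges
.as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}
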