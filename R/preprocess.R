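#' Sliding-window quality trimming
#'
#' Scans each read 5' to 3' in windows of `qual_window` bases and truncates
#' the read at the start of the first window whose mean Phred quality falls
#' below `qual_threshold`. Reads whose surviving length is below `min_len`
#' are dropped; survivors are capped at `max_len` bases (barcode included).
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33 strings).
#' @param config A [pipeline_config()] object.
#' @return The filtered data.frame; attribute `log` holds named counts
#'   (`input`, `truncated`, `dropped_short`, `kept`).
#' @export
quality_trim <- function(reads, config = pipeline_config()) {
  if (nrow(reads) == 0L) {
    attr(reads, "log") <- c(input = 0L, truncated = 0L, dropped_short = 0L,
                            kept = 0L)
    return(reads)
  }
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("malformed input: sequence and quality lengths differ")
  w <- config$qual_window
  qs <- lapply(reads$qual, function(s) utf8ToInt(s) - 33L)
  means <- data.table::frollmean(qs, n = w, align = "left")
  cut_len <- vapply(seq_along(qs), function(i) {
    m <- means[[i]]
    bad <- which(!is.na(m) & m < config$qual_threshold)
    if (length(bad)) bad[1] - 1L else length(qs[[i]])
  }, integer(1))
  keep_len <- pmin(cut_len, config$max_len)
  ok <- keep_len >= config$min_len
  out <- reads[ok, , drop = FALSE]
  out$seq <- substr(out$seq, 1L, keep_len[ok])
  out$qual <- substr(out$qual, 1L, keep_len[ok])
  rownames(out) <- NULL
  attr(out, "log") <- c(input = nrow(reads),
                        truncated = sum(cut_len < nchar(reads$seq)),
                        dropped_short = sum(!ok), kept = sum(ok))
  out
}

#' Split reads into random barcode and genomic insert
#'
#' The first `barcode_length` bases (with their qualities) become the
#' barcode; the remainder is the insert. Reads too short to leave at least
#' one insert base are dropped and counted.
#'
#' @inheritParams quality_trim
#' @return data.frame with `id`, `barcode`, `seq`, `qual` (insert only);
#'   attribute `n_dropped` counts reads without an insert.
#' @export
extract_barcode <- function(reads, config = pipeline_config()) {
  bl <- config$barcode_length
  ok <- nchar(reads$seq) >= bl + 1L
  out <- reads[ok, , drop = FALSE]
  out$barcode <- substr(out$seq, 1L, bl)
  out$seq <- substring(out$seq, bl + 1L)
  out$qual <- substring(out$qual, bl + 1L)
  rownames(out) <- NULL
  out <- out[, c("id", "barcode", "seq", "qual")]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Exact both-strand alignment of inserts on a small genome
#'
#' Searches every insert for exact matches on both strands of the supplied
#' genome (Biostrings `PDict`/`matchPDict`, grouped by insert width). A
#' uniquely matching insert yields a tag with mapping quality 42 and
#' `stop5` equal to the 0-based genomic coordinate of the read's 5' base
#' (for minus-strand matches, the rightmost matched base). Inserts matching
#' two or more loci are reported at their first locus with mapping quality
#' 0; non-matching inserts are dropped.
#'
#' @param reads data.frame from [extract_barcode()].
#' @param genome Named `DNAStringSet`.
#' @return Tag data.frame (`id`, `chrom`, `strand`, `stop5`, `barcode`,
#'   `mapq`); attribute `n_unaligned` counts dropped reads.
#' @export
naive_align <- function(reads, genome) {
  if (nrow(reads) > 0L && any(nchar(reads$seq) == 0L))
    stop("empty insert")
  n <- nrow(reads)
  chrom <- character(n); strand <- character(n)
  stop5 <- rep(NA_integer_, n); nhit <- integer(n)
  if (n > 0L) {
    widths <- nchar(reads$seq)
    for (wd in unique(widths)) {
      idx <- which(widths == wd)
      ins <- Biostrings::DNAStringSet(reads$seq[idx])
      fd <- Biostrings::PDict(ins)
      rd <- Biostrings::PDict(Biostrings::reverseComplement(ins))
      for (ch in names(genome)) {
        subj <- genome[[ch]]
        mf <- Biostrings::matchPDict(fd, subj)
        mr <- Biostrings::matchPDict(rd, subj)
        cf <- S4Vectors::elementNROWS(mf)
        cr <- S4Vectors::elementNROWS(mr)
        hit_f <- which(cf > 0L)
        for (k in hit_f) {
          i <- idx[k]
          if (is.na(stop5[i])) {
            chrom[i] <- ch; strand[i] <- "+"
            stop5[i] <- BiocGenerics::start(mf[[k]])[1] - 1L
          }
        }
        hit_r <- which(cr > 0L)
        for (k in hit_r) {
          i <- idx[k]
          if (is.na(stop5[i])) {
            chrom[i] <- ch; strand[i] <- "-"
            stop5[i] <- BiocGenerics::end(mr[[k]])[1] - 1L
          }
        }
        nhit[idx] <- nhit[idx] + cf + cr
      }
    }
  }
  aligned <- nhit > 0L
  out <- data.frame(id = reads$id[aligned], chrom = chrom[aligned],
                    strand = strand[aligned], stop5 = stop5[aligned],
                    barcode = reads$barcode[aligned],
                    mapq = ifelse(nhit[aligned] == 1L, 42L, 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unaligned") <- sum(!aligned)
  out
}

#' Mapping-quality filter
#'
#' Retains tags whose mapping quality is at least `mapq_min` (default 21,
#' i.e. mapq > 20, keeping uniquely aligned reads); input order preserved.
#'
#' @param tags Tag data.frame.
#' @param config A [pipeline_config()] object.
#' @return Filtered tag data.frame.
#' @export
filter_mapq <- function(tags, config = pipeline_config()) {
  out <- tags[tags$mapq >= config$mapq_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Barcode-aware PCR-duplicate removal
#'
#' Among tags sharing the same (chrom, strand, stop5, barcode) key, the
#' first-encountered tag is kept and the rest are removed. Tags differing
#' in any key component are all retained. Idempotent.
#'
#' @param tags Tag data.frame carrying a `barcode` column.
#' @return Deduplicated tag data.frame; attribute `n_duplicates` counts
#'   removed rows.
#' @export
deduplicate <- function(tags) {
  if (is.null(tags$barcode) || any(is.na(tags$barcode)))
    stop("missing barcode: deduplication requires a barcode per tag")
  key <- paste(tags$chrom, tags$strand, tags$stop5, tags$barcode,
               sep = "\r")
  keep <- !duplicated(key)
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(!keep)
  out
}

#' Full read-preprocessing chain
#'
#' Quality trimming, barcode extraction, exact alignment, mapping-quality
#' filtering and barcode deduplication in one call, with a per-stage count
#' log.
#'
#' @param reads Raw read data.frame (`id`, `seq`, `qual`).
#' @param genome Named `DNAStringSet`.
#' @param config A [pipeline_config()] object.
#' @return A list with `tags` (final tag data.frame) and `log` (named
#'   integer vector of stage counts).
#' @export
preprocess_reads <- function(reads, genome, config = pipeline_config()) {
  trimmed <- quality_trim(reads, config)
  tlog <- attr(trimmed, "log")
  bc <- extract_barcode(trimmed, config)
  aligned <- naive_align(bc, genome)
  uniq <- filter_mapq(aligned, config)
  dedup <- deduplicate(uniq)
  log <- c(input = unname(tlog["input"]),
           after_trim = unname(tlog["kept"]),
           dropped_short = unname(tlog["dropped_short"]),
           no_insert = attr(bc, "n_dropped"),
           aligned = nrow(aligned),
           unaligned = attr(aligned, "n_unaligned"),
           mapq_pass = nrow(uniq),
           duplicates_removed = attr(dedup, "n_duplicates"),
           final_tags = nrow(dedup))
  list(tags = dedup, log = log)
}
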