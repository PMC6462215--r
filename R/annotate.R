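#' Assign peaks to gene-relative categories
#'
#' A peak overlapping a gene body by at least 1 bp is `within_gene`
#' (largest overlap wins across genes; ties go to the lexicographically
#' smallest `gene_id`). Otherwise, if the distance to the nearest gene edge
#' is at most `flank` bases (boundary inclusive), the peak is
#' `upstream_5kb` or `downstream_5kb` according to which side of the gene
#' it lies on and the gene's strand; ties across genes break by smallest
#' distance then smallest `gene_id`. Peaks farther than `flank` from every
#' gene are `intergenic`. Peaks on chromosomes absent from the gene model
#' are marked `intergenic` with `unplaced = TRUE`.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @param config A [pipeline_config()] object (supplies `flank`).
#' @return `peaks` with added `category`, `gene_id`, `distance`,
#'   `unplaced` columns.
#' @export
annotate_peaks <- function(peaks, genes, config = pipeline_config()) {
  flank <- config$flank
  n <- nrow(peaks)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  unplaced <- rep(FALSE, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) {
      unplaced[i] <- !peaks$chrom[i] %in% genes$chrom
      next
    }
    ps <- peaks$start[i]; pe <- peaks$end[i]
    ov <- pmin(pe, g$end) - pmax(ps, g$start)
    if (any(ov > 0L)) {
      hit <- which(ov > 0L)
      best <- hit[order(-ov[hit], g$gene_id[hit])][1]
      category[i] <- "within_gene"
      gene_id[i] <- g$gene_id[best]
      distance[i] <- 0L
      next
    }
    d <- ifelse(pe <= g$start, g$start - pe, ps - g$end)
    best <- order(d, g$gene_id)[1]
    if (d[best] <= flank) {
      left_of_gene <- pe <= g$start[best]
      up <- (left_of_gene & g$strand[best] == "+") |
        (!left_of_gene & g$strand[best] == "-")
      category[i] <- if (up) "upstream_5kb" else "downstream_5kb"
      gene_id[i] <- g$gene_id[best]
      distance[i] <- d[best]
    } else {
      distance[i] <- d[best]
    }
  }
  out <- peaks
  out$category <- category
  out$gene_id <- gene_id
  out$distance <- distance
  out$unplaced <- unplaced
  out
}

#' Per-gene peak counts and single/multiple summary
#'
#' Counts how many gene-linked peaks (categories `within_gene`,
#' `upstream_5kb`, `downstream_5kb`) each gene carries and summarises how
#' many genes have exactly one versus two or more associated peaks.
#'
#' @param annotated Output of [annotate_peaks()].
#' @return A list with `per_gene` (data.frame `gene_id`, `n_peaks`) and
#'   `summary` (named vector `single`, `multiple`).
#' @export
genes_with_peaks <- function(annotated) {
  linked <- annotated[annotated$category %in%
                        c("within_gene", "upstream_5kb", "downstream_5kb"),
                      , drop = FALSE]
  if (nrow(linked) == 0L) {
    return(list(per_gene = data.frame(gene_id = character(),
                                      n_peaks = integer()),
                summary = c(single = 0L, multiple = 0L)))
  }
  tab <- table(linked$gene_id)
  per_gene <- data.frame(gene_id = names(tab),
                         n_peaks = as.integer(tab),
                         stringsAsFactors = FALSE)
  per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       summary = c(single = sum(per_gene$n_peaks == 1L),
                   multiple = sum(per_gene$n_peaks >= 2L)))
}
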