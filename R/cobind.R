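#' Two-factor peak overlap counts
#'
#' A peak in one set overlaps when it shares at least 1 bp of genomic
#' intersection (half-open arithmetic) with any peak of the other set;
#' counts are reported from each set's perspective, as drawn in
#' area-proportional Venn diagrams.
#'
#' @param peaks_a,peaks_b Peak data.frames.
#' @return A list: `n_a`, `n_b`, `n_a_only`, `n_b_only`,
#'   `n_a_overlapping`, `n_b_overlapping`, and `pairs`, a data.frame of
#'   overlapping index pairs (`a_idx`, `b_idx`).
#' @export
overlap_sets <- function(peaks_a, peaks_b) {
  n_a <- nrow(peaks_a); n_b <- nrow(peaks_b)
  if (n_a == 0L || n_b == 0L) {
    return(list(n_a = n_a, n_b = n_b, n_a_only = n_a, n_b_only = n_b,
                n_a_overlapping = 0L, n_b_overlapping = 0L,
                pairs = data.frame(a_idx = integer(), b_idx = integer())))
  }
  hits <- GenomicRanges::findOverlaps(.as_gr(peaks_a), .as_gr(peaks_b))
  a_hit <- unique(S4Vectors::queryHits(hits))
  b_hit <- unique(S4Vectors::subjectHits(hits))
  list(n_a = n_a, n_b = n_b,
       n_a_only = n_a - length(a_hit), n_b_only = n_b - length(b_hit),
       n_a_overlapping = length(a_hit), n_b_overlapping = length(b_hit),
       pairs = data.frame(a_idx = S4Vectors::queryHits(hits),
                          b_idx = S4Vectors::subjectHits(hits)))
}

#' Percentage ratio of two counts, half-up to one decimal
#'
#' @param numerator_count,denominator_count Non-negative counts;
#'   denominator must be positive.
#' @return `100 * n / d` rounded half-up to one decimal place.
#' @export
count_ratio <- function(numerator_count, denominator_count) {
  if (denominator_count <= 0) stop("denominator must be positive")
  floor(1000 * numerator_count / denominator_count + 0.5) / 10
}

#' Midpoint-referenced co-positioning coverage distributions
#'
#' Restricted to reference peaks of factor A that overlap at least one
#' region of factor B (sites bound by both molecules), uses each reference
#' midpoint `floor((start + end) / 2)` as origin and tallies, for each
#' factor, every genomic position covered by that factor's regions at the
#' site (union over regions overlapping the reference), as offsets clipped
#' to `cobind_halfwidth` bases either side.
#'
#' @param reference_peaks_a Reference peak data.frame (factor A).
#' @param regions_a,regions_b Binding-region data.frames (peaks or border
#'   pairs converted to `chrom`/`start`/`end`) for factors A and B.
#' @param config A [pipeline_config()] object.
#' @return A list with `a` and `b`: data.frames `offset`, `count`, `norm`
#'   over the full offset grid, plus `n_sites`.
#' @export
midpoint_coverage <- function(reference_peaks_a, regions_a, regions_b,
                              config = pipeline_config()) {
  hw <- config$cobind_halfwidth
  offsets <- seq.int(-hw, hw)
  tally_a <- integer(length(offsets))
  tally_b <- integer(length(offsets))
  n_sites <- 0L
  if (nrow(reference_peaks_a) > 0L && nrow(regions_b) > 0L) {
    ref_gr <- .as_gr(reference_peaks_a)
    b_gr <- .as_gr(regions_b)
    a_gr <- if (nrow(regions_a)) .as_gr(regions_a) else NULL
    keep <- GenomicRanges::countOverlaps(ref_gr, b_gr) > 0L
    refs <- reference_peaks_a[keep, , drop = FALSE]
    n_sites <- nrow(refs)
    for (i in seq_len(n_sites)) {
      m <- (refs$start[i] + refs$end[i]) %/% 2L
      tally_a <- tally_a + .site_cover(refs[i, ], regions_a, m, hw)
      tally_b <- tally_b + .site_cover(refs[i, ], regions_b, m, hw)
    }
  }
  mk <- function(cnt) {
    tot <- sum(cnt)
    data.frame(offset = offsets, count = cnt,
               norm = if (tot > 0) cnt / tot else rep(0, length(cnt)))
  }
  list(a = mk(tally_a), b = mk(tally_b), n_sites = n_sites)
}

# union coverage of `regions` overlapping one reference site, as offset
# counts relative to midpoint m, clipped to +/-hw
.site_cover <- function(ref, regions, m, hw) {
  cnt <- integer(2L * hw + 1L)
  if (nrow(regions) == 0L) return(cnt)
  r <- regions[regions$chrom == ref$chrom &
                 regions$end > ref$start & regions$start < ref$end,
               , drop = FALSE]
  if (nrow(r) == 0L) return(cnt)
  covered <- logical(2L * hw + 1L)
  for (k in seq_len(nrow(r))) {
    lo <- max(r$start[k] - m, -hw); hi <- min(r$end[k] - 1L - m, hw)
    if (lo <= hi) covered[(lo + hw + 1L):(hi + hw + 1L)] <- TRUE
  }
  as.integer(covered)
}

#' Similarity of two offset coverage distributions
#'
#' Jensen-Shannon divergence (natural log, so bounded by `log(2)`) and the
#' Pearson correlation of the normalized per-offset masses.
#'
#' @param d1,d2 Distribution data.frames from [midpoint_coverage()]
#'   (`offset`, `count`, `norm`) on the same offset grid.
#' @return A list with `jsd` and `correlation`.
#' @export
distribution_similarity <- function(d1, d2) {
  if (!identical(d1$offset, d2$offset))
    stop("distributions must share the same offset grid")
  if (sum(d1$count) == 0 || sum(d2$count) == 0)
    stop("zero-total distribution")
  p <- d1$norm; q <- d2$norm
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log(x[i] / y[i]))
  }
  list(jsd = 0.5 * kl(p, m) + 0.5 * kl(q, m),
       correlation = stats::cor(p, q))
}

#' Border pairs as binding-region intervals
#'
#' Convenience conversion of [call_border_pairs()] output to the
#' `chrom`/`start`/`end` layout the co-positioning functions expect.
#'
#' @param pairs Border-pair data.frame.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
pairs_as_regions <- function(pairs) {
  data.frame(chrom = pairs$chrom, start = pairs$plus_border,
             end = pairs$minus_border, stringsAsFactors = FALSE)
}
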