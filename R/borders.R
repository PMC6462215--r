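#' Detect strand-specific exonuclease-stop borders
#'
#' Within a genomic interval, reports the positions that are local maxima
#' of the strand's 5'-stop counts: count at least `min_count`, strictly
#' greater than every count in the 3 bases to the left and at least as
#' great as every count in the 3 bases to the right (so plateau ties break
#' leftmost).
#'
#' @param profile A `stop_profile`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param min_count Minimum stop count at a border.
#' @param within 0-based half-open interval `c(start, end)` to search;
#'   defaults to the whole chromosome.
#' @return data.frame with `pos` (0-based) and `count`.
#' @export
detect_borders <- function(profile, chrom, strand, min_count = 5L,
                           within = NULL) {
  counts <- if (strand == "+") profile$plus[[chrom]] else
    profile$minus[[chrom]]
  if (is.null(counts)) stop("unknown chromosome: ", chrom)
  L <- length(counts)
  if (is.null(within)) within <- c(0L, L)
  lo <- max(0L, within[1]); hi <- min(L, within[2])
  if (hi <= lo)
    return(data.frame(pos = integer(), count = integer()))
  cand <- lo + which(counts[(lo + 1L):hi] >= min_count) - 1L  # 0-based
  keep <- vapply(cand, function(p) {
    v <- counts[p + 1L]
    left <- if (p >= 1L) counts[seq.int(max(1L, p - 2L), p)] else
      integer(0)                                      # positions p-3..p-1
    right <- if (p + 2L <= L) counts[seq.int(p + 2L, min(L, p + 4L))] else
      integer(0)                                      # positions p+1..p+3
    (!length(left) || v > max(left)) && (!length(right) || v >= max(right))
  }, logical(1))
  data.frame(pos = cand[keep], count = counts[cand[keep] + 1L])
}

#' Pair plus- and minus-strand borders into protected regions
#'
#' Greedy matching by ascending plus-border position: each plus border is
#' paired with the nearest downstream minus border whose separation falls
#' inside `border_width_range`; every border is used at most once.
#' Unpairable borders are dropped and recorded in the `unpaired` attribute.
#'
#' @param plus_borders,minus_borders data.frames from [detect_borders()].
#' @param config A [pipeline_config()] object.
#' @return data.frame of border pairs: `plus_border`, `minus_border`,
#'   `width`, `support_plus`, `support_minus`.
#' @export
pair_borders <- function(plus_borders, minus_borders,
                         config = pipeline_config()) {
  rng <- config$border_width_range
  p <- plus_borders[order(plus_borders$pos), , drop = FALSE]
  m <- minus_borders[order(minus_borders$pos), , drop = FALSE]
  used <- rep(FALSE, nrow(m))
  out <- list()
  for (i in seq_len(nrow(p))) {
    sep <- m$pos - p$pos[i]
    ok <- which(!used & sep >= rng[1] & sep <= rng[2])
    if (!length(ok)) next
    jj <- ok[which.min(sep[ok])]
    used[jj] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      plus_border = p$pos[i], minus_border = m$pos[jj],
      width = m$pos[jj] - p$pos[i],
      support_plus = p$count[i], support_minus = m$count[jj])
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(plus_border = integer(), minus_border = integer(),
               width = integer(), support_plus = integer(),
               support_minus = integer())
  paired_plus <- pairs$plus_border
  attr(pairs, "unpaired") <- list(
    plus = setdiff(p$pos, paired_plus),
    minus = m$pos[!used])
  pairs
}

#' Border-pair detection across called peaks
#'
#' Searches each peak interval (extended by `border_margin`) for plus- and
#' minus-strand borders and pairs them. The per-peak minimum border count
#' defaults to `max(5, 2 x local background stop rate)`, the local rate
#' being the mean strand-specific stop count over the search interval.
#'
#' @param profile A `stop_profile` built from deduplicated tags.
#' @param peaks Peak data.frame.
#' @param config A [pipeline_config()] object.
#' @param min_count Fixed minimum border count; `NULL` for the adaptive
#'   default.
#' @return data.frame of pairs with `chrom`, `pair_id`, `peak_name` plus
#'   the [pair_borders()] columns.
#' @export
call_border_pairs <- function(profile, peaks, config = pipeline_config(),
                              min_count = NULL) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    L <- profile$chrom_sizes[[ch]]
    lo <- max(0L, peaks$start[i] - config$border_margin)
    hi <- min(L, peaks$end[i] + config$border_margin)
    mc <- min_count
    if (is.null(mc)) {
      bg <- (mean(profile$plus[[ch]][(lo + 1L):hi]) +
               mean(profile$minus[[ch]][(lo + 1L):hi])) / 2
      mc <- max(5, ceiling(2 * bg))
    }
    pb <- detect_borders(profile, ch, "+", mc, within = c(lo, hi))
    mb <- detect_borders(profile, ch, "-", mc, within = c(lo, hi))
    pr <- pair_borders(pb, mb, config)
    if (nrow(pr)) {
      pr$chrom <- ch
      pr$peak_name <- peaks$name[i]
      out[[length(out) + 1L]] <- pr
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(plus_border = integer(), minus_border = integer(),
               width = integer(), support_plus = integer(),
               support_minus = integer(), chrom = character(),
               peak_name = character())
  if (nrow(pairs)) pairs$pair_id <- sprintf("bp_%d", seq_len(nrow(pairs)))
  else pairs$pair_id <- character()
  rownames(pairs) <- NULL
  pairs[, c("chrom", "plus_border", "minus_border", "width",
            "support_plus", "support_minus", "peak_name", "pair_id")]
}
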