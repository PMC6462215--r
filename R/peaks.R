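#' Build per-strand 5'-stop profiles
#'
#' Tallies, per chromosome and strand, how many tags stop (5' end) at each
#' position.
#'
#' @param tags Tag data.frame (`chrom`, `strand`, `stop5`).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A `stop_profile` object: list with `chrom_sizes`, `plus` and
#'   `minus` (named lists of per-position integer count vectors).
#' @export
build_stop_profile <- function(tags, chrom_sizes) {
  if (nrow(tags) > 0L) {
    bad <- !(tags$chrom %in% names(chrom_sizes))
    if (any(bad)) stop("tag chromosome not in chrom_sizes: ",
                       tags$chrom[bad][1])
    over <- tags$stop5 < 0L | tags$stop5 >= chrom_sizes[tags$chrom]
    if (any(over)) stop("tag position beyond chromosome size")
  }
  prof <- list(chrom_sizes = chrom_sizes,
               plus = list(), minus = list())
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    for (s in c("plus", "minus")) {
      sym <- if (s == "plus") "+" else "-"
      sel <- tags$chrom == ch & tags$strand == sym
      prof[[s]][[ch]] <- tabulate(tags$stop5[sel] + 1L, nbins = L)
    }
  }
  class(prof) <- "stop_profile"
  prof
}

.profile_total <- function(profile) {
  sum(vapply(profile$plus, sum, numeric(1))) +
    sum(vapply(profile$minus, sum, numeric(1)))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values (monotone in p, clipped to \[0, 1\]).
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) && (any(is.na(pvalues)) ||
                          any(pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Poisson local-lambda enrichment peak calling
#'
#' Slides a `peak_width` window (step `peak_step`) over the pooled-strand
#' treatment stop counts and tests each window count against a Poisson null
#' whose rate is the depth-scaled maximum of the control's genome-wide rate
#' and its local rates in 1-kb and 10-kb windows centred on the candidate
#' (a sparse-control pseudocount of `peak_pseudocount` reads per local
#' window floors the estimates). Window p-values are converted to
#' Benjamini-Hochberg q-values; overlapping significant windows are merged
#' and each merged region is reported as one fixed-width peak centred on
#' its summit, the position of maximal (+/-5 bp smoothed) pooled tag count,
#' ties broken leftmost.
#'
#' @param treatment,control `stop_profile` objects over identical
#'   chromosome sizes.
#' @param config A [pipeline_config()] object.
#' @return Peak data.frame: `chrom`, `start`, `end` (0-based half-open,
#'   width `peak_width`), `name`, `summit`, `pvalue`, `qvalue`,
#'   `fold_enrichment`, sorted by coordinate.
#' @export
call_peaks <- function(treatment, control, config = pipeline_config()) {
  if (!identical(treatment$chrom_sizes, control$chrom_sizes))
    stop("treatment and control must share chromosome sizes")
  W <- config$peak_width
  step <- config$peak_step
  pseudo <- config$peak_pseudocount
  t_total <- .profile_total(treatment)
  c_total <- .profile_total(control)
  if (c_total == 0 && pseudo <= 0)
    stop("control has zero depth; supply control reads or set a positive ",
         "peak_pseudocount")
  G <- sum(control$chrom_sizes)
  scale <- if (c_total > 0) t_total / c_total else 1

  cand <- list()
  for (ch in names(treatment$chrom_sizes)) {
    L <- treatment$chrom_sizes[[ch]]
    if (L < W) next
    tc <- treatment$plus[[ch]] + treatment$minus[[ch]]
    cc <- control$plus[[ch]] + control$minus[[ch]]
    ct <- c(0, cumsum(tc))
    cctl <- c(0, cumsum(cc))
    starts <- seq.int(0L, L - W, by = step)
    wcount <- ct[starts + W + 1L] - ct[starts + 1L]
    center <- starts + W %/% 2L

    loc_rate <- function(V) {
      lo <- pmax(0L, center - V %/% 2L)
      hi <- pmin(L, center + V %/% 2L)
      pmax(cctl[hi + 1L] - cctl[lo + 1L], pseudo) * W / (hi - lo)
    }
    lam_bg <- max(c_total, pseudo) * W / G
    lambda <- scale * pmax(lam_bg, loc_rate(1000L), loc_rate(10000L))
    pv <- stats::ppois(wcount - 1, lambda, lower.tail = FALSE)
    cand[[ch]] <- data.frame(chrom = ch, start = starts, count = wcount,
                             lambda = lambda, pvalue = pv,
                             stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(.empty_peaks())
  all <- do.call(rbind, cand)
  all$qvalue <- bh_fdr(all$pvalue)
  sig <- all[all$qvalue < config$peak_fdr & all$count > 0, , drop = FALSE]
  if (nrow(sig) == 0L) return(.empty_peaks())

  peaks <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    L <- treatment$chrom_sizes[[ch]]
    tc <- treatment$plus[[ch]] + treatment$minus[[ch]]
    sm <- as.numeric(stats::filter(tc, rep(1 / 11, 11), sides = 2))
    sm[is.na(sm)] <- -Inf
    grp <- cumsum(c(1L, diff(s$start) >= W))
    for (g in unique(grp)) {
      rows <- s[grp == g, , drop = FALSE]
      rs <- min(rows$start); re <- max(rows$start) + W  # region, half-open
      idx <- (rs + 1L):re
      cand <- which(sm[idx] == max(sm[idx]))
      cand <- cand[tc[idx][cand] == max(tc[idx][cand])]  # raw-count tie-break
      summit <- rs + cand[1] - 1L                        # 0-based, leftmost
      start <- summit - W %/% 2L
      start <- max(0L, min(start, L - W))
      best <- which.min(rows$pvalue)
      cnt <- sum(tc[(start + 1L):(start + W)])
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch, start = start, end = start + W,
        summit = summit, pvalue = rows$pvalue[best],
        qvalue = rows$qvalue[best],
        fold_enrichment = cnt / rows$lambda[best],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, peaks)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("peak_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "summit", "pvalue", "qvalue",
          "fold_enrichment")]
}

.empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), summit = integer(), pvalue = numeric(),
             qvalue = numeric(), fold_enrichment = numeric(),
             stringsAsFactors = FALSE)
}

#' Replicate-reproducibility filter for pooled peak calls
#'
#' Keeps peaks from the pooled-replicate call that directly overlap (at
#' least 1 bp) a peak in at least `min_support` of the individual replicate
#' calls.
#'
#' @param pooled_peaks Peak data.frame from the pooled call.
#' @param replicate_peak_sets List of per-replicate peak data.frames.
#' @param min_support Minimum number of supporting replicates.
#' @return The supported subset of `pooled_peaks`.
#' @export
reproducible_peaks <- function(pooled_peaks, replicate_peak_sets,
                               min_support = 2L) {
  if (min_support > length(replicate_peak_sets))
    stop("min_support exceeds the number of replicate sets")
  if (nrow(pooled_peaks) == 0L) return(pooled_peaks)
  gr <- .as_gr(pooled_peaks)
  support <- rep(0L, nrow(pooled_peaks))
  for (rep_set in replicate_peak_sets) {
    if (nrow(rep_set) == 0L) next
    hit <- GenomicRanges::countOverlaps(gr, .as_gr(rep_set)) > 0L
    support <- support + as.integer(hit)
  }
  out <- pooled_peaks[support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}
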