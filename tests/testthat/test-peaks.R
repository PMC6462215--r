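test_that("stop profiles tally 5' ends per strand and position", {
  cs <- c(chrS = 500L)
  tags <- data.frame(chrom = "chrS", strand = c("+", "+", "+"),
                     stop5 = c(100L, 100L, 100L), barcode = "A", mapq = 42L)
  prof <- build_stop_profile(tags, cs)
  expect_equal(prof$plus$chrS[101], 3L)
  expect_equal(sum(prof$plus$chrS) + sum(prof$minus$chrS), 3)

  empty <- build_stop_profile(tags[0, ], cs)
  expect_true(all(empty$plus$chrS == 0L) && all(empty$minus$chrS == 0L))

  tags2 <- random_tags(1000, seed = 8, n_pos = 400L)
  cs2 <- c(chr1 = 400L, chr2 = 400L)
  prof2 <- build_stop_profile(tags2, cs2)
  # brute-force per-position tally
  for (ch in names(cs2)) for (sym in c("+", "-")) {
    v <- if (sym == "+") prof2$plus[[ch]] else prof2$minus[[ch]]
    sel <- tags2[tags2$chrom == ch & tags2$strand == sym, ]
    expect_equal(v, vapply(0:399, function(p) sum(sel$stop5 == p),
                           integer(1)))
  }
  bad <- data.frame(chrom = "chrS", strand = "+", stop5 = 600L,
                    barcode = "A", mapq = 42L)
  expect_error(build_stop_profile(bad, cs), "beyond chromosome")
})

test_that("identical treatment and control yield no peaks", {
  L <- 100000L
  tags <- withr::with_seed(2, uniform_tags(3000, L))
  prof <- build_stop_profile(tags, c(chrS = L))
  expect_equal(nrow(call_peaks(prof, prof)), 0L)
})

test_that("an enriched window is called with the exact Poisson tail", {
  L <- 200000L
  cfg <- pipeline_config()
  # deterministic uniform control: one tag every 100 bp
  ctrl <- data.frame(chrom = "chrS", strand = "+",
                     stop5 = seq.int(50L, L - 50L, by = 100L),
                     barcode = "A", mapq = 42L)
  treat <- data.frame(chrom = "chrS", strand = "+",
                      stop5 = rep(100000L, 30L), barcode = "A", mapq = 42L)
  tp <- build_stop_profile(treat, c(chrS = L))
  cp <- build_stop_profile(ctrl, c(chrS = L))
  peaks <- call_peaks(tp, cp, cfg)
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$summit, 100000L)
  # independent lambda derivation per the documented rule: depth-scaled
  # max of genome-wide, 1 kb and 10 kb control rates (pseudocount floor)
  scale <- nrow(treat) / nrow(ctrl)
  lam_bg <- nrow(ctrl) * cfg$peak_width / L
  lam_1k <- max(10, cfg$peak_pseudocount) * cfg$peak_width / 1000
  lam_10k <- max(100, cfg$peak_pseudocount) * cfg$peak_width / 10000
  lambda <- scale * max(lam_bg, lam_1k, lam_10k)
  expect_equal(peaks$pvalue,
               ppois(30 - 1, lambda, lower.tail = FALSE))
  expect_lt(peaks$qvalue, 0.05)
  expect_equal(peaks$end - peaks$start, cfg$peak_width)
})

test_that("q-values follow the Benjamini-Hochberg step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle on random p-values
  p <- withr::with_seed(7, runif(50))
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  oracle <- numeric(n); oracle[o] <- pmin(1, q_sorted)
  expect_equal(bh_fdr(p), oracle)
})

test_that("scaling up an enriched site never removes its peak", {
  L <- 100000L
  ctrl <- data.frame(chrom = "chrS", strand = "+",
                     stop5 = seq.int(50L, L - 50L, by = 100L),
                     barcode = "A", mapq = 42L)
  cp <- build_stop_profile(ctrl, c(chrS = L))
  for (depth in c(20L, 40L, 80L)) {
    treat <- data.frame(chrom = "chrS", strand = "+",
                        stop5 = rep(50000L, depth), barcode = "A",
                        mapq = 42L)
    tp <- build_stop_profile(treat, c(chrS = L))
    pk <- call_peaks(tp, cp)
    expect_equal(nrow(pk), 1L)
    expect_equal(pk$summit, 50000L)
  }
})

test_that("peak intervals are fixed-width and stay inside the chromosome", {
  L <- 50000L
  ctrl <- data.frame(chrom = "chrS", strand = "+",
                     stop5 = seq.int(50L, L - 50L, by = 100L),
                     barcode = "A", mapq = 42L)
  # enriched site at the chromosome edge
  treat <- data.frame(chrom = "chrS", strand = "+",
                      stop5 = rep(10L, 40L), barcode = "A", mapq = 42L)
  pk <- call_peaks(build_stop_profile(treat, c(chrS = L)),
                   build_stop_profile(ctrl, c(chrS = L)))
  expect_equal(nrow(pk), 1L)
  expect_true(all(pk$start >= 0L & pk$end <= L))
  expect_true(all(pk$end - pk$start == pipeline_config()$peak_width))
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
})

test_that("replicate-reproducibility filtering needs >=1 bp in >=2 sets", {
  mk <- function(starts) data.frame(
    chrom = "chrS", start = starts, end = starts + 100L,
    name = sprintf("p%d", seq_along(starts)), summit = starts + 50L,
    pvalue = 1e-6, qvalue = 1e-5, fold_enrichment = 10)
  A <- 0L; B <- 200L; C <- 400L
  pooled <- mk(c(A, B, C))
  # identical replicate sets: everything kept
  expect_equal(nrow(reproducible_peaks(pooled, list(pooled, pooled, pooled))),
               3L)
  # toy sets {A,B}, {B,C}, {B} -> only B survives min_support = 2
  reps <- list(mk(c(A, B)), mk(c(B, C)), mk(B))
  out <- reproducible_peaks(pooled, reps)
  expect_equal(out$start, B)
  # brute-force overlap-support oracle
  support <- vapply(seq_len(3), function(i) {
    sum(vapply(reps, function(r)
      any(pmin(pooled$end[i], r$end) - pmax(pooled$start[i], r$start) > 0),
      logical(1)))
  }, integer(1))
  expect_equal(out$start, pooled$start[support >= 2L])
  # a peak in only 1 of 3 replicates is excluded
  expect_false(A %in% out$start)
  expect_error(reproducible_peaks(pooled, reps, min_support = 4L),
               "min_support")
})
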