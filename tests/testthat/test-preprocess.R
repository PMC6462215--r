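test_that("quality trimming follows the sliding-window rule", {
  cfg <- pipeline_config()
  # uniformly good long read is capped at 59 bases
  r <- mk_reads(strrep("A", 70), phred_string(rep(35L, 70)))
  out <- quality_trim(r, cfg)
  expect_equal(nchar(out$seq), 59L)
  # short good read is dropped outright
  r2 <- mk_reads(strrep("A", 20), phred_string(rep(35L, 20)))
  expect_equal(nrow(quality_trim(r2, cfg)), 0L)
  # mixed-quality read truncated at the first failing window
  q3 <- c(rep(35L, 30), rep(10L, 10))
  r3 <- mk_reads(strrep("A", 40), phred_string(q3))
  out3 <- quality_trim(r3, cfg)
  # brute-force first window with mean < 20
  cut <- length(q3)
  for (i in seq_len(length(q3) - cfg$qual_window + 1L)) {
    if (mean(q3[i:(i + cfg$qual_window - 1L)]) < cfg$qual_threshold) {
      cut <- i - 1L; break
    }
  }
  expect_equal(nchar(out3$seq), min(cut, cfg$max_len))
  # malformed record
  bad <- mk_reads("ACGT", phred_string(rep(35L, 3)))
  expect_error(quality_trim(bad, cfg), "malformed")
})

test_that("trimming matches an exhaustive window-scan oracle", {
  cfg <- pipeline_config()
  reads <- withr::with_seed(5, {
    n <- 60L
    lens <- sample(15:80, n, replace = TRUE)
    mk_reads(vapply(lens, function(l)
               paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
               character(1)),
             vapply(lens, function(l)
               phred_string(sample(15:40, l, TRUE)), character(1)))
  })
  out <- quality_trim(reads, cfg)
  oracle <- lapply(seq_len(nrow(reads)), function(i) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    cut <- length(q)
    for (s in seq_len(max(0L, length(q) - cfg$qual_window + 1L))) {
      if (mean(q[s:(s + cfg$qual_window - 1L)]) < cfg$qual_threshold) {
        cut <- s - 1L; break
      }
    }
    keep <- min(cut, cfg$max_len)
    if (keep < cfg$min_len) NULL else substr(reads$seq[i], 1L, keep)
  })
  expected <- as.character(unlist(oracle[!vapply(oracle, is.null,
                                                 logical(1))]))
  expect_gt(length(expected), 0L)
  expect_equal(out$seq, expected)
  # output length is never outside {dropped} U [min_len, max_len]
  expect_true(all(nchar(out$seq) >= cfg$min_len &
                    nchar(out$seq) <= cfg$max_len))
})

test_that("barcode extraction splits reads at the configured length", {
  cfg <- pipeline_config()
  r <- mk_reads(c(paste0(strrep("G", 9), strrep("A", 50)),
                  paste0(strrep("G", 9), strrep("A", 21)),
                  strrep("G", 9)),
                c(phred_string(rep(35L, 59)), phred_string(rep(35L, 30)),
                  phred_string(rep(35L, 9))))
  out <- extract_barcode(r, cfg)
  expect_equal(nrow(out), 2L)
  expect_equal(out$barcode, rep(strrep("G", 9), 2))
  expect_equal(nchar(out$seq), c(50L, 21L))
  expect_equal(attr(out, "n_dropped"), 1L)
})

test_that("exact alignment reports the 5' stop with the strand convention", {
  sim <- sim_config(genome_length = 10000L, n_sites = 0L, seed = 13)
  genome <- simulate_genome(sim)
  gchar <- as.character(genome[[1]])

  fwd <- substr(gchar, 1001, 1030)  # 0-based [1000, 1030)
  stopifnot(length(Biostrings::matchPattern(fwd, genome[[1]])) == 1)
  r <- data.frame(id = "f", barcode = "AAAAAAAAA", seq = fwd,
                  qual = phred_string(rep(35L, 30)))
  tag <- naive_align(r, genome)
  expect_equal(tag$strand, "+")
  expect_equal(tag$stop5, 1000L)
  expect_equal(tag$mapq, 42L)

  # reverse-complement of [2000, 2050): minus-strand 5' end at 2049
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gchar, 2001, 2050))))
  r2 <- data.frame(id = "r", barcode = "AAAAAAAAA", seq = rcs,
                   qual = phred_string(rep(35L, 50)))
  tag2 <- naive_align(r2, genome)
  expect_equal(tag2$strand, "-")
  expect_equal(tag2$stop5, 2049L)

  # repeated insert -> mapq 0, then removed by the mapq filter
  gd <- paste0(gchar, substr(gchar, 3001, 3040))
  dup_genome <- Biostrings::DNAStringSet(gd); names(dup_genome) <- "chrS"
  r3 <- data.frame(id = "d", barcode = "AAAAAAAAA",
                   seq = substr(gchar, 3001, 3040),
                   qual = phred_string(rep(35L, 40)))
  tag3 <- naive_align(r3, dup_genome)
  expect_equal(tag3$mapq, 0L)
  expect_equal(nrow(filter_mapq(tag3)), 0L)

  expect_error(naive_align(data.frame(id = "e", barcode = "A", seq = "",
                                      qual = ""), genome),
               "empty insert")
})

test_that("the mapping-quality filter is strict at the boundary", {
  tags <- data.frame(chrom = "chrS", strand = "+", stop5 = 0:2,
                     barcode = "AAAAAAAAA", mapq = c(20L, 21L, 42L))
  out <- filter_mapq(tags)
  expect_equal(out$mapq, c(21L, 42L))
  empty <- tags[0, ]
  expect_equal(nrow(filter_mapq(empty)), 0L)
})

test_that("deduplication keeps one tag per (chrom, strand, stop, barcode)", {
  two <- data.frame(chrom = "chr1", strand = "+", stop5 = 100L,
                    barcode = "AAACCCGGG", mapq = 42L)[c(1, 1), ]
  expect_equal(nrow(deduplicate(two)), 1L)
  diffbc <- data.frame(chrom = "chr1", strand = "+", stop5 = 100L,
                       barcode = c("AAACCCGGG", "TTTCCCGGG"), mapq = 42L)
  expect_equal(nrow(deduplicate(diffbc)), 2L)
  nobc <- data.frame(chrom = "chr1", strand = "+", stop5 = 1L, mapq = 42L)
  expect_error(deduplicate(nobc), "barcode")

  tags <- random_tags(10, seed = 3)
  out <- deduplicate(tags)
  # brute-force unique-key oracle: first index of every distinct key
  key <- paste(tags$chrom, tags$strand, tags$stop5, tags$barcode)
  first <- sort(vapply(split(seq_along(key), key), min, integer(1)))
  expect_equal(out, tags[first, ], ignore_attr = TRUE)
  # idempotent, and output is a subset of input
  expect_equal(deduplicate(out), out, ignore_attr = TRUE)
  expect_true(all(paste(out$chrom, out$strand, out$stop5, out$barcode)
                  %in% key))
})

test_that("post-dedup tag count matches the planted duplication rate", {
  sim <- tiny_sim(duplication_rate = 0.2, border_jitter = 0L)
  pl <- plant_sites(simulate_genome(sim), sim)
  rd <- simulate_nexus_reads(pl$genome, pl$truth, "CORT", "MR", sim)
  rd$tags$mapq <- 42L
  total <- nrow(rd$tags)
  kept <- nrow(deduplicate(rd$tags))
  # jitter-free duplicates are exact re-emissions; only rare barcode
  # collisions can shift the count
  expect_lt(abs(kept / total - (1 - sim$duplication_rate)), 0.02)
})
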