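# shared fixtures for the suite; everything is generated in code

tiny_sim <- function(...) {
  args <- utils::modifyList(list(genome_length = 60000L, n_sites = 20L,
                                 reads_per_bound_site = 20L, seed = 11L),
                            list(...))
  do.call(sim_config, args)
}

# random tag table over a couple of chromosomes
random_tags <- function(n, seed = 1, n_pos = 1000L, n_barcodes = 50L) {
  withr::with_seed(seed, {
    data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stop5 = sample.int(n_pos, n, replace = TRUE) - 1L,
      barcode = sample(replicate(n_barcodes,
                                 paste(sample(c("A", "C", "G", "T"), 9,
                                              replace = TRUE),
                                       collapse = "")),
                       n, replace = TRUE),
      mapq = 42L, stringsAsFactors = FALSE)
  })
}

# uniform-rate tag set used for null peak-calling simulations
uniform_tags <- function(n, L, chrom = "chrS") {
  data.frame(chrom = chrom,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stop5 = sample.int(L, n, replace = TRUE) - 1L,
             barcode = "AAAAAAAAA", mapq = 42L, stringsAsFactors = FALSE)
}

# read set with explicit quality strings
mk_reads <- function(seqs, quals, ids = sprintf("r%d", seq_along(seqs))) {
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

phred_string <- function(q) {
  paste(vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1)),
        collapse = "")
}
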