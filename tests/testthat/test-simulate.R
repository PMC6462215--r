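test_that("the generator is fully deterministic under a fixed seed", {
  sim <- tiny_sim()
  g1 <- simulate_genome(sim); g2 <- simulate_genome(sim)
  expect_identical(as.character(g1), as.character(g2))
  p1 <- plant_sites(g1, sim); p2 <- plant_sites(g2, sim)
  expect_identical(p1$truth, p2$truth)
  expect_identical(as.character(p1$genome), as.character(p2$genome))
  r1 <- simulate_nexus_reads(p1$genome, p1$truth, "CORT", "MR", sim)
  r2 <- simulate_nexus_reads(p2$genome, p2$truth, "CORT", "MR", sim)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$tags, r2$tags)
})

test_that("genome composition follows the configured GC content", {
  gc1 <- sim_config(genome_length = 2000L, gc_content = 1, seed = 4)
  g <- simulate_genome(gc1)
  freq <- Biostrings::letterFrequency(g[[1]], c("A", "C", "G", "T"))
  expect_equal(unname(freq[["A"]] + freq[["T"]]), 0)

  gc41 <- sim_config(genome_length = 1000000L, gc_content = 0.41, seed = 4)
  g2 <- simulate_genome(gc41)
  obs <- (Biostrings::letterFrequency(g2[[1]], c("C", "G"))[["C"]] +
            Biostrings::letterFrequency(g2[[1]], c("C", "G"))[["G"]]) / 1e6
  sd3 <- 3 * sqrt(0.41 * 0.59 / 1e6)
  expect_lt(abs(obs - 0.41), sd3)

  cfg <- tiny_sim(); cfg$genome_length <- 500L
  expect_error(simulate_genome(cfg), "genome_length")
})

test_that("site planting writes motifs and draws classes as configured", {
  sim0 <- tiny_sim(n_sites = 0L)
  g <- simulate_genome(sim0)
  out <- plant_sites(g, sim0)
  expect_equal(nrow(out$truth), 0L)
  expect_identical(as.character(out$genome), as.character(g))

  simf <- tiny_sim(motif_fraction = 1)
  g1 <- simulate_genome(simf)
  out1 <- plant_sites(g1, simf)
  expect_true(all(out1$truth$has_motif))
  seqchar <- as.character(out1$genome[[1]])
  for (i in seq_len(nrow(out1$truth))) {
    mid <- (out1$truth$start[i] + out1$truth$end[i]) %/% 2
    got <- substr(seqchar, mid - 7 + 1, mid + 7 + 1)
    expect_match(got, "^AGAACA[ACGT]{3}TGTTCT$")
  }

  simc <- sim_config(genome_length = 200000L, n_sites = 500L,
                     co_binding_fraction = 0.66, seed = 9)
  out2 <- plant_sites(simulate_genome(simc), simc)
  frac <- mean(out2$truth$shared)
  expect_lt(abs(frac - 0.66), 3 * sqrt(0.66 * 0.34 / 500))
  # sites never overlap
  expect_true(all(diff(out2$truth$start) >= simc$protected_width))
})

test_that("read emission respects borders, dosage and duplication", {
  # no bound sites, no background -> no reads
  sim <- tiny_sim(background_read_rate = 0, duplication_rate = 0)
  sim$occupancy <- list(vehicle = c(MR = 0, GR = 0),
                        CORT = c(MR = 0, GR = 0),
                        washout = c(MR = 0, GR = 0))
  pl <- plant_sites(simulate_genome(sim), sim)
  rd <- simulate_nexus_reads(pl$genome, pl$truth, "CORT", "MR", sim)
  expect_equal(nrow(rd$reads), 0L)
  expect_error(simulate_nexus_reads(pl$genome, pl$truth, "dex", "MR", sim),
               "unknown condition")

  # jitter-free emission: 5' stops equal planted borders exactly, and the
  # read count is exactly n_bound * reads_per_bound_site
  simj <- tiny_sim(border_jitter = 0L, duplication_rate = 0,
                   background_read_rate = 0)
  plj <- plant_sites(simulate_genome(simj), simj)
  rdj <- simulate_nexus_reads(plj$genome, plj$truth, "CORT", "MR", simj)
  nb <- sum(plj$truth$bound_MR_CORT)
  expect_equal(nrow(rdj$reads), nb * simj$reads_per_bound_site)
  tg <- merge(rdj$tags, plj$truth[, c("site_id", "border_plus",
                                      "border_minus")],
              by.x = "origin", by.y = "site_id")
  expect_true(all(tg$stop5[tg$strand == "+"] ==
                    tg$border_plus[tg$strand == "+"]))
  expect_true(all(tg$stop5[tg$strand == "-"] ==
                    tg$border_minus[tg$strand == "-"]))
  # linear scaling in reads_per_bound_site
  simj2 <- tiny_sim(border_jitter = 0L, duplication_rate = 0,
                    background_read_rate = 0, reads_per_bound_site = 40L)
  rdj2 <- simulate_nexus_reads(plj$genome, plj$truth, "CORT", "MR", simj2)
  expect_equal(nrow(rdj2$reads), 2L * nrow(rdj$reads))

  # one site, 100 duplicate-free reads: all (pos, strand, barcode) triples
  # distinct, so dedup leaves the count unchanged
  sim1 <- sim_config(genome_length = 10000L, n_sites = 1L,
                     reads_per_bound_site = 100L, duplication_rate = 0,
                     background_read_rate = 0, seed = 21,
                     occupancy = list(CORT = c(MR = 1, GR = 1)))
  pl1 <- plant_sites(simulate_genome(sim1), sim1)
  rd1 <- simulate_nexus_reads(pl1$genome, pl1$truth, "CORT", "MR", sim1)
  expect_equal(nrow(rd1$tags), 100L)
  rd1$tags$mapq <- 42L
  expect_equal(nrow(deduplicate(rd1$tags)), 100L)
})

test_that("default occupancy encodes the receptor affinity asymmetry", {
  sim <- sim_config()
  occ <- sim$occupancy
  # GR high only under the pulse; MR substantially retained after washout
  expect_gt(occ$CORT[["GR"]], 0.5)
  expect_lt(occ$washout[["GR"]], 0.1)
  expect_gt(occ$washout[["MR"]], 5 * occ$washout[["GR"]])
  # emitted GR read counts mirror that: washout << CORT
  pl <- plant_sites(simulate_genome(sim), sim)
  rc <- simulate_nexus_reads(pl$genome, pl$truth, "CORT", "GR", sim)
  rw <- simulate_nexus_reads(pl$genome, pl$truth, "washout", "GR", sim)
  site_c <- sum(rc$tags$origin != "background")
  site_w <- sum(rw$tags$origin != "background")
  expect_lt(site_w, 0.2 * site_c)
})

test_that("truth-table border geometry matches the protected width", {
  sim <- tiny_sim()
  pl <- plant_sites(simulate_genome(sim), sim)
  expect_true(all(pl$truth$border_minus - pl$truth$border_plus ==
                    sim$protected_width))
})
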