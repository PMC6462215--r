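#' @importFrom withr with_seed
NULL

# Seed offsets keep the per-stage RNG streams of one experiment distinct
# while remaining fully determined by config$seed.
.seed_offset <- c(genome = 11L, sites = 23L, genes = 31L, input = 97L)

.stage_seed <- function(cfg, stage, extra = 0L) {
  (cfg$seed + .seed_offset[[stage]] + as.integer(extra)) %% .Machine$integer.max
}

#' Canonical GRE consensus used for motif planting
#'
#' The palindromic 15-mer glucocorticoid response element
#' `AGAACAnnnTGTTCT`; the three `n` positions are filled with random bases
#' at planting time.
#'
#' @return A character scalar.
#' @export
gre_consensus <- function() "AGAACANNNTGTTCT"

#' Simulate a background genome
#'
#' Draws an i.i.d. nucleotide sequence of the configured length and GC
#' content. Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A named [Biostrings::DNAStringSet] with one chromosome `chrS`.
#' @export
simulate_genome <- function(config) {
  if (config$genome_length < 1000L)
    stop("configuration error: genome_length must be >= 1000")
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seq <- withr::with_seed(.stage_seed(config, "genome"), {
    paste(sample(names(p), config$genome_length, replace = TRUE, prob = p),
          collapse = "")
  })
  gen <- Biostrings::DNAStringSet(seq)
  names(gen) <- "chrS"
  gen
}

#' Plant binding sites and build the ground-truth table
#'
#' Places `n_sites` non-overlapping protected regions on the genome (one
#' per equal-width genome bin, so sites never collide and stay separable),
#' writes the GRE consensus at the midpoint of a `motif_fraction` share of
#' sites, classifies each site as shared or factor-exclusive according to
#' `co_binding_fraction`, and draws per-condition bound flags from the
#' occupancy table. Site intervals are 0-based half-open
#' `[border_plus, border_minus)` with width `protected_width`.
#'
#' @param genome A `DNAStringSet` from [simulate_genome()].
#' @param config A [sim_config()] object.
#' @return A list with `genome` (motifs written in) and `truth`, a
#'   data.frame with one row per site: `chrom`, `start`, `end`, `site_id`,
#'   `has_motif`, `shared`, `factor_class`, one `bound_<factor>_<condition>`
#'   logical column per combination, `border_plus`, `border_minus`.
#' @export
plant_sites <- function(genome, config) {
  L <- Biostrings::width(genome)[1]
  chrom <- names(genome)[1]
  w <- config$protected_width
  n <- config$n_sites
  conditions <- names(config$occupancy)
  factors <- names(config$occupancy[[1]])

  if (n == 0L) {
    truth <- empty_truth(conditions, factors)
    return(list(genome = genome, truth = truth))
  }

  margin <- max(config$read_length + config$border_jitter + 10L, 60L)
  bin <- floor(L / n)
  if (bin < w + 2L * margin)
    stop("n_sites too large for non-overlapping placement on this genome")

  res <- withr::with_seed(.stage_seed(config, "sites"), {
    offs <- sample.int(bin - w - 2L * margin + 1L, n, replace = TRUE) - 1L
    start <- (seq_len(n) - 1L) * bin + margin + offs   # 0-based
    end <- start + w
    has_motif <- stats::runif(n) < config$motif_fraction
    shared <- stats::runif(n) < config$co_binding_fraction
    excl <- sample(factors, n, replace = TRUE)
    factor_class <- ifelse(shared, "both", excl)
    bound <- list()
    for (cond in conditions) {
      for (fac in factors) {
        capable <- shared | factor_class == fac
        bound[[paste0("bound_", fac, "_", cond)]] <-
          capable & (stats::runif(n) < config$occupancy[[cond]][[fac]])
      }
    }
    fill <- sample(c("A", "C", "G", "T"), 3L * n, replace = TRUE)
    list(start = start, end = end, has_motif = has_motif, shared = shared,
         factor_class = factor_class, bound = bound, fill = fill)
  })

  truth <- data.frame(
    chrom = chrom, start = res$start, end = res$end,
    site_id = sprintf("site_%04d", seq_len(n)),
    has_motif = res$has_motif, shared = res$shared,
    factor_class = res$factor_class,
    stringsAsFactors = FALSE
  )
  for (nm in names(res$bound)) truth[[nm]] <- res$bound[[nm]]
  truth$border_plus <- truth$start
  truth$border_minus <- truth$end

  # write the GRE consensus centred on the site midpoint
  seqchar <- as.character(genome[[1]])
  cons <- gre_consensus()
  ml <- nchar(cons)
  for (i in which(truth$has_motif)) {
    mid <- floor((truth$start[i] + truth$end[i]) / 2)
    s1 <- mid - floor(ml / 2) + 1L  # 1-based motif start
    motif <- cons
    nn <- res$fill[(3L * (i - 1L) + 1L):(3L * i)]
    substr(motif, 7L, 9L) <- paste(nn, collapse = "")
    substr(seqchar, s1, s1 + ml - 1L) <- motif
  }
  out <- Biostrings::DNAStringSet(seqchar)
  names(out) <- chrom
  list(genome = out, truth = truth)
}

empty_truth <- function(conditions, factors) {
  truth <- data.frame(chrom = character(), start = integer(),
                      end = integer(), site_id = character(),
                      has_motif = logical(), shared = logical(),
                      factor_class = character(), stringsAsFactors = FALSE)
  for (cond in conditions) for (fac in factors)
    truth[[paste0("bound_", fac, "_", cond)]] <- logical()
  truth$border_plus <- integer()
  truth$border_minus <- integer()
  truth
}

.random_barcodes <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Simulate ChIP-nexus reads for one factor in one condition
#'
#' Emits `reads_per_bound_site` reads for every site bound by `factor` in
#' `condition`: plus-strand reads stop (5' end) at the planted left border
#' and minus-strand reads at the right border, each jittered uniformly by
#' up to `border_jitter` bases, reflecting lambda-exonuclease digestion
#' halting at the crosslinked protein. Each read is a random barcode
#' prepended to a `read_length`-base genomic insert. A `duplication_rate`
#' share of the final read pool are PCR re-emissions with identical
#' position, strand and barcode, and background reads are scattered
#' uniformly at `background_read_rate` per kb.
#'
#' @param genome `DNAStringSet` (motif-planted).
#' @param truth Truth table from [plant_sites()].
#' @param condition Condition name present in the occupancy table.
#' @param factor Factor name present in the occupancy table.
#' @param config A [sim_config()] object.
#' @return A list with `reads` (data.frame `id`, `seq`, `qual`) and `tags`,
#'   the expected post-alignment tag table (`chrom`, `strand`, `stop5`,
#'   `barcode`, `origin`).
#' @export
simulate_nexus_reads <- function(genome, truth, condition, factor, config) {
  conditions <- names(config$occupancy)
  factors <- names(config$occupancy[[1]])
  if (!condition %in% conditions)
    stop("unknown condition: ", condition)
  if (!factor %in% factors)
    stop("unknown factor: ", factor)
  col <- paste0("bound_", factor, "_", condition)
  bound <- truth[truth[[col]], , drop = FALSE]
  extra <- 100L + 10L * match(condition, conditions) + match(factor, factors)
  withr::with_seed(.stage_seed(config, "input", extra), {
    .emit_reads(genome, bound, config,
                sample_id = paste0(factor, "_", condition))
  })
}

#' Simulate an input (no-immunoprecipitation) control sample
#'
#' Background-only reads at `input_read_rate` per kb, uniform positions and
#' random strands, used for peak-calling normalization.
#'
#' @inheritParams simulate_nexus_reads
#' @return Same structure as [simulate_nexus_reads()].
#' @export
simulate_input_reads <- function(genome, config) {
  conditions <- names(config$occupancy)
  factors <- names(config$occupancy[[1]])
  empty <- empty_truth(conditions, factors)
  withr::with_seed(.stage_seed(config, "input"), {
    .emit_reads(genome, empty, config, sample_id = "input",
                background_rate = config$input_read_rate)
  })
}

.emit_reads <- function(genome, bound_sites, config, sample_id,
                        background_rate = config$background_read_rate) {
  L <- Biostrings::width(genome)[1]
  chrom <- names(genome)[1]
  rl <- config$read_length
  j <- config$border_jitter

  n_b <- nrow(bound_sites)
  rps <- config$reads_per_bound_site
  pos <- integer(0); str <- character(0); origin <- character(0)
  if (n_b > 0L && rps > 0L) {
    per_site_strand <- sample(c("+", "-"), n_b * rps, replace = TRUE)
    site_idx <- rep(seq_len(n_b), each = rps)
    jit <- if (j > 0L) sample(seq(-j, j), n_b * rps, replace = TRUE) else 0L
    pos <- ifelse(per_site_strand == "+",
                  bound_sites$border_plus[site_idx],
                  bound_sites$border_minus[site_idx]) + jit
    str <- per_site_strand
    origin <- bound_sites$site_id[site_idx]
  }

  n_bg <- stats::rpois(1L, background_rate * L / 1000)
  if (n_bg > 0L) {
    bg_str <- sample(c("+", "-"), n_bg, replace = TRUE)
    # keep the whole insert on the chromosome
    bg_pos <- ifelse(bg_str == "+",
                     sample.int(L - rl, n_bg, replace = TRUE) - 1L,
                     sample.int(L - rl, n_bg, replace = TRUE) - 1L + rl - 1L)
    pos <- c(pos, bg_pos); str <- c(str, bg_str)
    origin <- c(origin, rep("background", n_bg))
  }

  n_u <- length(pos)
  bc <- .random_barcodes(n_u, config$barcode_length)

  # PCR duplicates: re-emit rows so that the duplicate share of the final
  # pool equals duplication_rate
  d <- config$duplication_rate
  if (d > 0 && n_u > 0L) {
    n_dup <- round(d / (1 - d) * n_u)
    if (n_dup > 0L) {
      dup_idx <- sample.int(n_u, n_dup, replace = TRUE)
      pos <- c(pos, pos[dup_idx]); str <- c(str, str[dup_idx])
      bc <- c(bc, bc[dup_idx]); origin <- c(origin, origin[dup_idx])
    }
  }

  n <- length(pos)
  if (n == 0L) {
    return(list(
      reads = data.frame(id = character(), seq = character(),
                         qual = character(), stringsAsFactors = FALSE),
      tags = data.frame(chrom = character(), strand = character(),
                        stop5 = integer(), barcode = character(),
                        origin = character(), stringsAsFactors = FALSE)))
  }

  seqchar <- as.character(genome[[1]])
  ins <- character(n)
  plus <- str == "+"
  if (any(plus))
    ins[plus] <- substring(seqchar, pos[plus] + 1L, pos[plus] + rl)
  if (any(!plus)) {
    sub <- substring(seqchar, pos[!plus] + 1L - (rl - 1L), pos[!plus] + 1L)
    ins[!plus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sub)))
  }
  qchar <- strrep(rawToChar(as.raw(config$base_quality + 33L)),
                  config$barcode_length + rl)
  reads <- data.frame(
    id = sprintf("%s:rd%06d", sample_id, seq_len(n)),
    seq = paste0(bc, ins),
    qual = qchar,
    stringsAsFactors = FALSE
  )
  tags <- data.frame(chrom = chrom, strand = str, stop5 = as.integer(pos),
                     barcode = bc, origin = origin, stringsAsFactors = FALSE)
  list(reads = reads, tags = tags)
}

#' Simulate simple gene models on the synthetic genome
#'
#' Places non-overlapping gene intervals (one per genome bin) with random
#' strands, for exercising the annotation stage. Purely structural: genes
#' carry no expression model.
#'
#' @param config A [sim_config()] object.
#' @param n_genes Number of genes; default one per 10 kb.
#' @param min_width,max_width Gene width range in bases.
#' @return A gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @export
simulate_gene_models <- function(config,
                                 n_genes = max(1L, config$genome_length %/% 10000L),
                                 min_width = 2000L, max_width = 6000L) {
  L <- config$genome_length
  bin <- L %/% n_genes
  if (bin <= max_width + 2L)
    stop("n_genes too large for non-overlapping gene placement")
  withr::with_seed(.stage_seed(config, "genes"), {
    wd <- sample(seq(min_width, max_width), n_genes, replace = TRUE)
    off <- vapply(bin - wd, function(m) sample.int(m, 1L) - 1L, integer(1))
    start <- (seq_len(n_genes) - 1L) * bin + off
    data.frame(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      chrom = "chrS", start = start, end = start + wd,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}
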