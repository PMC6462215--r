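#' Simulation configuration for synthetic ChIP-nexus experiments
#'
#' Bundles every knob of the synthetic data generator: genome composition,
#' planted binding sites, per-condition/per-factor occupancy probabilities,
#' read emission and PCR duplication. Defaults describe a two-factor
#' corticosteroid-receptor system (MR, GR) observed under three hormone
#' conditions: `vehicle`, a 20-min `CORT` pulse, and `washout` (pulse then
#' ligand removal). MR is the high-affinity receptor, so its default
#' occupancy is substantially retained after washout (0.30 vs 0.90 under
#' CORT), while the low-affinity GR collapses to near baseline (0.02).
#'
#' @param genome_length Genome size in bases (single synthetic chromosome).
#' @param gc_content GC fraction of the background genome.
#' @param n_sites Number of planted binding sites.
#' @param co_binding_fraction Fraction of sites accessible to both factors;
#'   the remainder are split evenly between MR-only and GR-only sites.
#' @param motif_fraction Fraction of sites carrying the planted GRE
#'   consensus at their midpoint.
#' @param protected_width Exonuclease-protected width in bases; the planted
#'   plus- and minus-strand borders are exactly this far apart.
#' @param occupancy Named list `condition -> c(MR = p, GR = p)` of binding
#'   probabilities. Conditions and factor names are taken from this object
#'   throughout the pipeline.
#' @param reads_per_bound_site ChIP-nexus reads emitted per bound site.
#' @param background_read_rate Background reads per kilobase in ChIP samples.
#' @param input_read_rate Reads per kilobase in the input (no-IP) control.
#' @param duplication_rate Fraction of emitted reads that are PCR duplicates
#'   (identical position, strand and barcode re-emissions).
#' @param border_jitter Maximum uniform jitter, in bases, of read 5' stops
#'   around the planted border.
#' @param barcode_length Random-barcode length in nucleotides.
#' @param read_length Genomic insert length in bases.
#' @param base_quality Constant Phred score of emitted bases.
#' @param seed Integer seed; every stochastic operation derives its RNG
#'   state from it, so a fixed seed reproduces the experiment exactly.
#'
#' @return An object of class `nexus_sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 200000L,
                       gc_content = 0.41,
                       n_sites = 100L,
                       co_binding_fraction = 0.66,
                       motif_fraction = 0.58,
                       protected_width = 30L,
                       occupancy = list(
                         vehicle = c(MR = 0.02, GR = 0.02),
                         CORT    = c(MR = 0.90, GR = 0.90),
                         washout = c(MR = 0.30, GR = 0.02)
                       ),
                       reads_per_bound_site = 50L,
                       background_read_rate = 0.5,
                       input_read_rate = 5,
                       duplication_rate = 0.1,
                       border_jitter = 2L,
                       barcode_length = 9L,
                       read_length = 50L,
                       base_quality = 35L,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    gc_content = gc_content,
    n_sites = as.integer(n_sites),
    co_binding_fraction = co_binding_fraction,
    motif_fraction = motif_fraction,
    protected_width = as.integer(protected_width),
    occupancy = occupancy,
    reads_per_bound_site = as.integer(reads_per_bound_site),
    background_read_rate = background_read_rate,
    input_read_rate = input_read_rate,
    duplication_rate = duplication_rate,
    border_jitter = as.integer(border_jitter),
    barcode_length = as.integer(barcode_length),
    read_length = as.integer(read_length),
    base_quality = as.integer(base_quality),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "nexus_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$genome_length) || cfg$genome_length <= 0)
    stop("configuration error: genome_length must be positive")
  fracs <- c(cfg$gc_content, cfg$co_binding_fraction, cfg$motif_fraction,
             cfg$duplication_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("configuration error: fractions must lie in [0, 1]")
  if (cfg$protected_width < 1)
    stop("configuration error: protected_width must be >= 1")
  if (cfg$duplication_rate >= 1)
    stop("configuration error: duplication_rate must be < 1")
  occ <- unlist(cfg$occupancy)
  if (any(occ < 0 | occ > 1))
    stop("configuration error: occupancy probabilities must lie in [0, 1]")
  facs <- lapply(cfg$occupancy, names)
  if (length(unique(facs)) != 1L)
    stop("configuration error: every condition must list the same factors")
  invisible(cfg)
}

#' Analysis pipeline configuration
#'
#' Holds every tunable parameter of the processing and analysis stages.
#' Defaults follow the conventional ChIP-nexus processing recipe for this
#' assay: sliding 4-base quality windows trimmed below mean Phred 20, reads
#' shorter than 29 bases dropped and reads capped at 59 bases (9-base
#' barcode plus 50-base insert), mapping quality above 20 to keep uniquely
#' aligned reads, peaks called at FDR 0.05 with a fixed 100-bp width,
#' gene annotation within a 5-kb flank, motif windows of +/-100 and
#' +/-200 bp around summits, border-pair widths between 10 and 100 bp and
#' co-positioning tallied up to 155 bases from the reference midpoint.
#'
#' @param qual_window Sliding-window width (bases) for quality trimming.
#' @param qual_threshold Minimum mean Phred score per window.
#' @param min_len Minimum surviving read length; shorter reads are dropped.
#' @param max_len Maximum read length; longer reads are truncated.
#' @param barcode_length Random-barcode length at the read 5' end.
#' @param mapq_min Minimum retained mapping quality (21 keeps mapq > 20).
#' @param peak_fdr Benjamini-Hochberg q-value cutoff for peak calls.
#' @param peak_width Fixed reported peak width in bases.
#' @param peak_step Candidate-window step in bases for peak scanning.
#' @param peak_pseudocount Control pseudocount (reads per lambda window)
#'   applied when the local control count is sparse.
#' @param flank Gene-annotation flank in bases (inclusive boundary).
#' @param motif_windows Summit half-windows (bases) used for motif scans.
#' @param border_width_range Allowed border-pair widths, `c(min, max)` bases.
#' @param border_margin Margin (bases) added around peaks when searching
#'   for borders.
#' @param cobind_halfwidth Half-width (bases) of the midpoint-referenced
#'   co-positioning window.
#'
#' @return An object of class `nexus_pipeline_config`.
#' @export
pipeline_config <- function(qual_window = 4L,
                            qual_threshold = 20,
                            min_len = 29L,
                            max_len = 59L,
                            barcode_length = 9L,
                            mapq_min = 21L,
                            peak_fdr = 0.05,
                            peak_width = 100L,
                            peak_step = 10L,
                            peak_pseudocount = 1,
                            flank = 5000L,
                            motif_windows = c(100L, 200L),
                            border_width_range = c(10L, 100L),
                            border_margin = 100L,
                            cobind_halfwidth = 155L) {
  if (min_len > max_len) stop("configuration error: min_len > max_len")
  if (peak_width <= 0 || flank <= 0 || any(motif_windows <= 0) ||
      cobind_halfwidth <= 0)
    stop("configuration error: windows must be positive")
  if (length(border_width_range) != 2L ||
      border_width_range[1] > border_width_range[2])
    stop("configuration error: border_width_range must be c(min, max)")
  cfg <- list(
    qual_window = as.integer(qual_window),
    qual_threshold = qual_threshold,
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    barcode_length = as.integer(barcode_length),
    mapq_min = as.integer(mapq_min),
    peak_fdr = peak_fdr,
    peak_width = as.integer(peak_width),
    peak_step = as.integer(peak_step),
    peak_pseudocount = peak_pseudocount,
    flank = as.integer(flank),
    motif_windows = as.integer(motif_windows),
    border_width_range = as.integer(border_width_range),
    border_margin = as.integer(border_margin),
    cobind_halfwidth = as.integer(cobind_halfwidth)
  )
  class(cfg) <- "nexus_pipeline_config"
  cfg
}
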