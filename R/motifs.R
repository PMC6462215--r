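#' Construct a position probability matrix object
#'
#' @param matrix Numeric 4 x L matrix, rows `A`, `C`, `G`, `T`; columns are
#'   per-position base probabilities (or counts, normalized internally).
#' @param name Motif name.
#' @param background Background base frequencies (length 4, sums to 1).
#' @param pseudocount Added to each cell before normalization.
#' @return An object of class `pwm`.
#' @export
make_pwm <- function(matrix, name = "motif",
                     background = rep(0.25, 4), pseudocount = 0) {
  m <- as.matrix(matrix) + pseudocount
  if (nrow(m) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(m) <- c("A", "C", "G", "T")
  m <- sweep(m, 2, colSums(m), "/")
  if (any(abs(colSums(m) - 1) > 1e-9))
    stop("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1")
  structure(list(name = name, matrix = m, background = background),
            class = "pwm")
}

#' Read a JASPAR-style plain-text matrix file
#'
#' Format: a `>name` header followed by four lines `A [ n n ... ]` etc.
#' Counts are converted to probabilities with a pseudocount.
#'
#' @param path Matrix file path.
#' @param pseudocount Added to each count before normalization.
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, pseudocount = 0.5) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  name <- sub("^>\\s*", "", ln[grepl("^>", ln)][1])
  rows <- lapply(c("A", "C", "G", "T"), function(b) {
    l <- ln[grepl(paste0("^", b, "\\b"), ln)][1]
    as.numeric(strsplit(gsub("[][]", " ", sub(paste0("^", b), "", l)),
                        "\\s+")[[1]] |> (\(x) x[nzchar(x)])())
  })
  make_pwm(do.call(rbind, rows), name = name, pseudocount = pseudocount)
}

#' The package's bundled consensus-derived probability matrices
#'
#' Returns one of the motif matrices shipped under `extdata/pwms/`. These
#' are synthetic consensus-derived matrices (GRE palindrome
#' `AGAACAnnnTGTTCT`, GATA `AGATAA`, AP-1 `TGACTCA`) built from the
#' standard literature consensus sequences, not copies of any curated
#' database release.
#'
#' @param name One of `"GRE"`, `"GATA3"`, `"AP1"`.
#' @return A `pwm` object.
#' @export
builtin_pwm <- function(name = c("GRE", "GATA3", "AP1")) {
  name <- match.arg(name)
  path <- system.file("extdata", "pwms",
                      paste0(name, "_consensus.jaspar"),
                      package = "nexuspipe", mustWork = TRUE)
  read_pwm(path)
}

.seq_codes <- function(sequence, mask_lowercase = FALSE) {
  s <- as.character(sequence)
  if (!mask_lowercase) s <- toupper(s)
  match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window with the log-odds `sum(log(p_base / q_base))`
#' (natural log) on the forward sequence and its reverse complement, and
#' reports windows scoring at least `min_score_fraction` of the maximal
#' achievable score. Windows containing non-ACGT bases are skipped; when
#' the matrix cannot score positively (e.g. equals the background) no hits
#' are reported.
#'
#' @param sequence Character scalar or `DNAString`.
#' @param pwm A `pwm` object.
#' @param min_score_fraction Hit threshold as a fraction of the maximal
#'   log-odds score.
#' @param mask_lowercase Treat lowercase (soft-masked) bases as N.
#' @return data.frame of hits: `start` (0-based window start on the
#'   forward sequence), `strand`, `score`.
#' @export
scan_pwm <- function(sequence, pwm, min_score_fraction = 0.8,
                     mask_lowercase = FALSE) {
  lo <- log(pwm$matrix / pwm$background)
  L <- ncol(lo)
  codes <- .seq_codes(sequence, mask_lowercase)
  n <- length(codes)
  empty <- data.frame(start = integer(), strand = character(),
                      score = numeric())
  if (n < L) return(empty)
  maxscore <- sum(apply(lo, 2, max))
  thr <- min_score_fraction * maxscore
  if (maxscore <= 0) return(empty)

  score_strand <- function(cd) {
    nw <- length(cd) - L + 1L
    s <- numeric(nw)
    for (j in seq_len(L)) s <- s + lo[cbind(cd[j:(j + nw - 1L)], j)]
    s
  }
  sf <- score_strand(codes)
  comp <- 5L - codes
  sr <- score_strand(rev(comp))
  hf <- which(!is.na(sf) & sf >= thr)
  hr <- which(!is.na(sr) & sr >= thr)
  out <- rbind(
    data.frame(start = hf - 1L, strand = rep("+", length(hf)),
               score = sf[hf]),
    data.frame(start = n - hr - L + 1L, strand = rep("-", length(hr)),
               score = sr[hr]))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.clip_window <- function(summit, halfwidth, L) {
  lo <- max(0L, summit - halfwidth)
  hi <- min(L, summit + halfwidth + 1L)  # half-open
  c(lo, hi)
}

#' Fraction of peaks with a motif hit near the summit
#'
#' Scans the `window` bases either side of each peak summit (clipped at
#' chromosome edges) and reports the fraction of peaks with at least one
#' hit.
#'
#' @param peaks Peak data.frame with `summit` positions.
#' @param genome Named `DNAStringSet`.
#' @param pwm A `pwm` object.
#' @param window Half-window in bases around the summit.
#' @param min_score_fraction Hit threshold (see [scan_pwm()]).
#' @return Fraction in \[0, 1\].
#' @export
motif_enrichment_fraction <- function(peaks, genome, pwm, window = 200L,
                                      min_score_fraction = 0.8) {
  if (nrow(peaks) == 0L) return(NA_real_)
  hit <- vapply(seq_len(nrow(peaks)), function(i) {
    ch <- peaks$chrom[i]
    L <- Biostrings::width(genome)[match(ch, names(genome))]
    w <- .clip_window(peaks$summit[i], window, L)
    s <- as.character(Biostrings::subseq(genome[[ch]], w[1] + 1L, w[2]))
    nrow(scan_pwm(s, pwm, min_score_fraction)) > 0L
  }, logical(1))
  mean(hit)
}

#' Summit-relative motif hit frequency profile
#'
#' Histograms the offsets of motif-hit centers from peak summits over
#' `[-halfwidth, +halfwidth]`, normalized by the number of peaks, so the
#' profile mass equals hits retained per peak.
#'
#' @inheritParams motif_enrichment_fraction
#' @param halfwidth Half-window in bases (at least the PWM length).
#' @return data.frame `offset`, `frequency`.
#' @export
motif_frequency_profile <- function(peaks, genome, pwm, halfwidth = 200L,
                                    min_score_fraction = 0.8) {
  L_m <- ncol(pwm$matrix)
  if (halfwidth < L_m) stop("halfwidth must be at least the PWM length")
  offsets <- seq.int(-halfwidth, halfwidth)
  cnt <- integer(length(offsets))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    L <- Biostrings::width(genome)[match(ch, names(genome))]
    w <- .clip_window(peaks$summit[i], halfwidth, L)
    s <- as.character(Biostrings::subseq(genome[[ch]], w[1] + 1L, w[2]))
    hits <- scan_pwm(s, pwm, min_score_fraction)
    if (nrow(hits) == 0L) next
    centers <- w[1] + hits$start + L_m %/% 2L
    off <- centers - peaks$summit[i]
    off <- off[off >= -halfwidth & off <= halfwidth]
    cnt <- cnt + tabulate(off + halfwidth + 1L, nbins = length(offsets))
  }
  data.frame(offset = offsets,
             frequency = if (nrow(peaks)) cnt / nrow(peaks) else
               rep(0, length(offsets)))
}
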