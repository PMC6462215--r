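---
title: "Methods: synthetic ChIP-nexus analysis of paired corticosteroid receptors"
author: "nexuspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ChIP-nexus analysis of paired corticosteroid receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The mineralocorticoid receptor (MR) and glucocorticoid receptor (GR) form a
dual sensor for circulating corticosteroids. MR binds ligand with high
affinity and is substantially occupied at low hormone levels; GR requires
the higher concentrations of a stress pulse. Both receptors recognise the
palindromic glucocorticoid response element (GRE, consensus
`AGAACAnnnTGTTCT`), often at shared genomic sites. ChIP-nexus resolves
their binding footprints at near-nucleotide resolution: lambda-exonuclease
digests immunoprecipitated DNA 5'-to-3' until it stalls at the crosslinked
protein, so the 5' ends of plus-strand reads pile up at the left edge of
the protected region and minus-strand 5' ends at the right edge, and a
random 9-nt barcode ligated to each molecule lets true PCR duplicates be
distinguished from independent fragments stopping at the same base.

`nexuspipe` implements the complete downstream analysis for such an
experiment — quality filtering, barcode deduplication, peak calling with
input normalization, gene-relative annotation, two-factor overlap and
hormone-condition retention, strand-specific border-pair detection,
midpoint-referenced co-positioning, and known-motif scanning — together
with a synthetic data generator so every stage can be validated against
planted ground truth at desk scale.

## The synthetic generator

`sim_config()` fixes the study conditions. A single synthetic chromosome
(default 200 kb, GC 0.41, matching a mammalian genome-wide average) hosts
`n_sites` (default 100) non-overlapping protected regions of
`protected_width` (default 30 bp, the middle of the 10–60 bp range typical
of receptor footprints). One site is placed uniformly inside each equal
genome bin; this guarantees non-overlap and keeps sites far enough apart
(≥ 2 kb at the defaults) that peak calls are unambiguous. Placement
margins keep every read insert on the chromosome.

Site properties are drawn independently per site:

* `co_binding_fraction` (default 0.66) of sites are accessible to both
  factors, the rest split evenly between MR-only and GR-only — mirroring
  the two-thirds direct GR–MR overlap such experiments observe;
* `motif_fraction` (default 0.58) of sites carry the GRE consensus written
  at the site midpoint (the observed share of GRE-bearing binding sites);
  the three `n` positions are filled randomly;
* occupancy per condition and factor is Bernoulli with the configured
  probability. The defaults — vehicle 0.02/0.02, CORT pulse 0.90/0.90,
  washout 0.30 (MR) / 0.02 (GR) — encode the affinity asymmetry: the
  planted washout/pulse retention ratios are about 33% for MR and about 2%
  for GR, the dynamics reported for this receptor pair.

Reads from a bound site stop at the planted borders with a uniform jitter
of ±2 bp by default: stop-position noise of real ChIP-nexus libraries is
not published, and ±2 bp yields realistic but recoverable profiles. Each
read is a fully random 9-nt barcode plus a 50-bp genomic insert at
constant Phred 35 (a low-quality-tail option exercises trimming); the
fixed/random composition of real ChIP-nexus barcodes is not described, so
fully random is assumed. PCR duplicates are exact re-emissions of existing
(position, strand, barcode) triples, injected so that the duplicate share
of the final pool equals `duplication_rate` (default 0.1); after perfect
deduplication the expected surviving fraction is therefore `1 − d`.
Background reads are uniform with random strand — the simplest null
consistent with the peak caller's assumptions; chromatin accessibility,
mappability and base-composition structure are deliberately not modelled.
The input control is background-only at `input_read_rate` (default
5 reads/kb, giving the control several-fold the ChIP background depth, as
input libraries usually do).

Everything derives from `seed`: each stage uses a fixed offset from it, so
a run is reproducible end to end while stages remain decoupled.

What passing recovery tests on these data do **not** show: robustness to
non-uniform background, repeat-induced multimapping, adapter read-through,
under- or over-digestion by the exonuclease, or antibody cross-reactivity.
They validate the arithmetic and the statistical machinery, not the wet
assay.

## Preprocessing

Trimming follows the sliding-window rule with the standard parameters for
this assay: scan 4-base windows 5'→3', truncate at the start of the first
window with mean Phred < 20, drop reads shorter than 29 bases, cap at 59
bases (9-bp barcode + 50-bp insert). Trimming precedes barcode splitting
because the 59-bp cap includes the barcode. The window is cut at its
start — the common `SLIDINGWINDOW` semantics implied by those parameters.

`naive_align()` performs exact both-strand substring search (Biostrings
`PDict`) and stands in for an external aligner on synthetic genomes:
unique matches get mapping quality 42, multi-mappers 0, and the
mapping-quality filter keeps tags with mapq > 20 (the strict inequality;
`mapq_min` is configurable). The 5' stop coordinate convention is: for a
minus-strand match covering `[s, e)` half-open, the 5' end is `e − 1`.

Deduplication collapses tags sharing (chromosome, strand, 5' stop,
barcode), keeping the first in input order — deterministic and
order-stable. The key uses the 5' stop only, matching the single-ligation
geometry of ChIP-nexus: both duplicate mates carry the same stop.

## Peak calling

The caller is a transparent Poisson local-lambda scanner in the MACS2
tradition (it does not promise output equality with any MACS2 release).
A `peak_width` (100 bp) window steps every 10 bp along the pooled-strand
stop counts. The null rate for a window is the treatment-depth-scaled
maximum of the control's genome-wide rate and its 1-kb and 10-kb local
rates centred on the candidate; sparse control windows are floored at
`peak_pseudocount` (1) read before conversion to a rate, and a zero-depth
control without a pseudocount is an error. The upper Poisson tail gives
the window p-value; Benjamini–Hochberg across all windows gives q-values
(the conventional q-value machinery for FDR < 0.05 peak reporting);
overlapping significant windows merge, and each merged region is reported
as one fixed-width peak centred on its summit.

The summit is the maximum of the ±5-bp-smoothed pooled counts. Ties on the
smoothed value are broken by the larger raw stop count and then leftmost:
a pure leftmost rule would pin a single-position stop spike to the left
edge of its 11-bp smoothing plateau, 5 bp off, whereas the raw-count
refinement recovers the spike exactly. Peaks are clipped (by shifting, to
preserve the fixed width) at chromosome ends. Both strands are pooled for
enrichment testing; strand separation is reserved for border detection.
Replicate support (`reproducible_peaks()`) keeps pooled peaks overlapping
≥ 1 bp with calls in at least two replicates.

## Borders and pairing

Within each called peak ± 100 bp, `detect_borders()` finds strand-specific
local maxima of the stop counts: at least `min_count` (adaptive default
`max(5, 2 × local background stop rate)`), strictly above the three
positions to the left and at least equal to the three to the right, so
plateau ties resolve leftmost. `pair_borders()` greedily pairs each plus
border (ascending) with the nearest downstream minus border whose
separation lies in `border_width_range` (default 10–100 bp, the observed
span of receptor protected regions, including the occasional 80–100 bp
GR footprint); each border is used once, leftovers are logged. The
published border-pair statistics of dedicated ChIP-exo callers are not
re-derived; this local-maximum scheme is deliberately simple and exactly
recoverable on planted data.

## Annotation, overlap and co-positioning

Peaks overlapping a gene body by ≥ 1 bp are `within_gene` (largest overlap,
then smallest gene id); otherwise a peak within `flank` (5 kb, boundary
inclusive — the open/closed convention is unstated in common usage, and
inclusive is chosen) of the nearest gene edge is `upstream_5kb` or
`downstream_5kb` resolved by gene strand; the rest are `intergenic`. The
four categories partition the peak set.

Two-factor overlap uses ≥ 1 bp intersection in half-open coordinates.
Retention across hormone conditions is the percentage ratio of peak
counts, rounded half-up to one decimal (`count_ratio()`), matching how
such percentages are conventionally printed.

Co-positioning: restricted to reference peaks (factor A, GR by default)
overlapping factor B, the midpoint `floor((start+end)/2)` anchors an
offset grid of ± `cobind_halfwidth` (155 bp, the maximal extent such
comparisons cover given footprint sizes and overlap degree). Every
position covered by a factor's regions at the site (union over regions,
counted once) contributes to its offset tally; distributions are
normalized and compared by Jensen–Shannon divergence (natural log, maximum
`log 2`) plus per-offset Pearson correlation. Border pairs are the
preferred region source when available, peaks otherwise — both inputs are
supported since either can represent a factor's binding region.

## Motif scanning

`scan_pwm()` computes the natural-log odds `sum(log(p/q))` at every window
on both strands, reporting windows at or above `min_score_fraction`
(default 0.8) of the maximal achievable score; windows containing N are
skipped, and a matrix that cannot score positively yields no hits. The
bundled GRE, GATA3 and AP-1 matrices are consensus-derived synthetic
probability matrices (85% consensus base, 5% others; `n` positions
uniform) built from the standard literature consensus strings — they are
not copies of a curated database release, and database-version-dependent
enrichment fractions on real data are out of scope. At the default
threshold the GRE matrix tolerates one mismatch in the 12 informative
positions; the analytic false-hit probability per window is the binomial
tail `P(Bin(12, 1/4) ≥ 11) ≈ 2×10⁻⁶`, so random hits contribute
negligibly to enrichment fractions. `motif_enrichment_fraction()` and
`motif_frequency_profile()` scan summit-centred windows (±100/±200 bp)
and histogram hit-centre offsets per peak.

## Numerical choices and degenerate inputs

* Even-width interval midpoints use the floor convention.
* `count_ratio` rounds half-up (base R's `round` is banker's rounding and
  would print 2.25 → 2.2).
* Empty inputs return empty, typed results (empty peak sets, zero-count
  distributions); zero-total distributions are an error for similarity.
* All randomness flows through per-stage offsets of the single seed.

## Problem sizes

The test-suite and acceptance runs use a 200-kb genome with 100 planted
sites at 50 reads per bound site (500 sites for motif-fraction recovery),
and 200 null peak-calling replicates for the false-positive rate. These
sizes give binomial standard errors of a few percent on every recovered
fraction while keeping a full run in tens of seconds on one core.

## Known limitations

Exact reproduction of published genome-wide peak counts is impossible by
construction: they depend on the deposited sequencing data and the precise
external-tool versions. The package therefore reproduces the *arithmetic*
of the printed ratios exactly and the *behaviour* (retention asymmetry,
overlap, border geometry, motif centring) on synthetic data. The aligner
is exact-match only (no mismatches or gaps); the caller has no fragment
model or broad-peak mode; annotation is gene-level, not transcript-level.
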