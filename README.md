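# nexuspipe

High-resolution ChIP-nexus analysis for a paired transcription-factor
system: the mineralocorticoid (MR) and glucocorticoid (GR) corticosteroid
receptors observed across hormone conditions (vehicle, a 20-min CORT
pulse, and washout). The package is aimed at analysts who want a fully
self-contained, desk-testable version of the standard processing chain —
and at method developers who need planted ground truth to validate each
stage.

ChIP-nexus reads carry a random 9-nt barcode followed by a genomic insert
whose 5' end marks where lambda-exonuclease digestion stalled at the
crosslinked protein. The pipeline implements:

* **simulate** — synthetic genomes, planted GRE-motif binding sites with
  per-condition occupancy (MR retained after washout, GR not), jittered
  border stops, PCR duplicates, background and input reads, plus a
  ground-truth table;
* **preprocess** — sliding-window quality trimming (4-base windows, mean
  Phred < 20 cut; < 29 bp dropped; capped at 59 bp), barcode extraction,
  exact both-strand alignment, mapq > 20 filtering, and barcode-aware
  deduplication on the (chrom, strand, 5' stop, barcode) key;
* **peaks** — Poisson local-lambda calling against a depth-scaled input
  control, `lambda_local = scale * max(lambda_bg, lambda_1kb, lambda_10kb)`,
  Benjamini–Hochberg FDR < 0.05, fixed 100-bp peaks centred on smoothed
  summits, and a two-of-three replicate-reproducibility filter;
* **borders** — strand-specific local maxima of 5'-stop counts paired
  greedily into protected regions 10–100 bp wide;
* **annotate** — within-gene / ±5-kb-flank / intergenic categories and
  per-gene peak multiplicity;
* **cobind** — ≥ 1 bp overlap Venn counts, washout/pulse retention
  percentages, and midpoint-referenced coverage distributions compared by
  Jensen–Shannon divergence and Pearson correlation (±155 bp window);
* **motifs** — log-odds PWM scanning (consensus-derived GRE/GATA3/AP-1
  matrices bundled), summit-window enrichment fractions and
  summit-relative frequency profiles.

## Worked example

```r
library(nexuspipe)
res <- run_pipeline(sim_config(seed = 3), outdir = "demo")
res$table1
#>   factor condition n_peaks n_genes_with_peaks genes_single_peak genes_multiple_peaks
#> 1     MR   vehicle       1                  1                 1                    0
#> 2     MR      CORT      78                 20                 1                   19
#> 3     MR   washout      29                 16                 7                    9
#> 4     GR   vehicle       1                  1                 1                    0
#> 5     GR      CORT      77                 20                 1                   19
#> 6     GR   washout       0                  0                 0                    0
res$retention
#>   factor condition ref_condition n_peaks ref_peaks pct_of_ref
#> 1     MR   vehicle          CORT       1        78        1.3
#> 2     MR   washout          CORT      29        78       37.2
#> 3     GR   vehicle          CORT       1        77        1.3
#> 4     GR   washout          CORT       0        77        0.0
```

Both factors bind almost nowhere without hormone, bind ~78 of the 100
planted sites during the CORT pulse (≈ 90% occupancy × 83 accessible
sites per factor), and diverge after washout: MR retains 37% of its pulse
peaks while GR retains none — the planted affinity asymmetry read back
through the full pipeline. The two factors' pulse peaks overlap at 57 of
77 GR sites (74%), and their midpoint-referenced coverage distributions
are near-identical (`res$copositioning$similarity`: JSD 0.001,
correlation 0.997). The bundled GRE matrix hits 61% of pulse peaks within
±100 bp of the summit, against a planted motif fraction of 0.58.

`run_pipeline()` writes `table1_peak_counts.tsv`, `peak_categories.tsv`,
`venn_counts.tsv`, `retention_ratios.tsv`, per-factor border-pair TSVs,
`copositioning_distributions.tsv`, `motif_fractions.tsv`, per-sample
narrowPeak files, the truth tables and a JSON run manifest into `outdir`.

Individual stages are plain functions: `quality_trim()`,
`extract_barcode()`, `naive_align()`, `filter_mapq()`, `deduplicate()`,
`build_stop_profile()`, `call_peaks()`, `bh_fdr()`,
`reproducible_peaks()`, `detect_borders()`, `pair_borders()`,
`annotate_peaks()`, `genes_with_peaks()`, `overlap_sets()`,
`count_ratio()`, `midpoint_coverage()`, `distribution_similarity()`,
`scan_pwm()`, `motif_enrichment_fraction()`, `motif_frequency_profile()`.

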