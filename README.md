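# episwitch

Coordinated histone-mark switching analysis around transcription start
sites, for two-condition ChIP-seq / expression studies.

## The problem

During oncogene-induced senescence (and in many other two-condition
comparisons), promoters switch epigenetic state in a coordinated way: genes
that lose the repressive mark H3K27me3 *and* gain the active mark H3K4me3
become strongly induced, genes that lose H3K4me3 *and* acquire de novo
H3K27me3 become repressed, while one-sided switches (bivalent promoters
resolving, unmarked promoters acquiring the repressive mark) leave
expression unchanged. `episwitch` provides the complete computational chain
for detecting and testing this structure, plus binding-site analysis of a
downstream transcription factor and a MeDIP promoter-methylation screen —
all exercisable on synthetic data with planted ground truth, so every stage
is testable without any external download.

It is aimed at computational biologists who have mapped reads (BED-like),
a one-TSS-per-gene annotation, and per-gene expression scores, and want a
reproducible, threshold-explicit promoter-state analysis rather than a
generic peak caller.

## The statistics at the core

* **Windowed RPM.** The mark level at centre $c$ is
  $10^6 \cdot \#\{p_i \in [c - \lfloor w/2\rfloor, c - \lfloor w/2\rfloor + w)\}/N$,
  reads counted by 5′ position, $N$ the uniquely-mapped denominator. A
  gene's promoter statistic is the exact maximum over all integer centres
  within ±2 kb of its TSS (window 300 bp for H3K4me3, 500 bp for
  H3K27me3/MeDIP).
* **Status and switch calling.** Plus/minus thresholds (4/3 RPM for
  H3K4me3, 1.5/1 for H3K27me3); a transition requires crossing both
  (loss: >hi then <lo; gain is the mirror image). Category pairs form
  `K27_to_K4`, `Bi_to_K4`, `K4_to_K27`, `none_to_K27`, plus residuals —
  a partition of the gene set.
* **Rank enrichment.** Genes ranked by fold change (baseline vs mean of
  condition time points, global normalization to mean 100); each category
  is tested inside its panel (all K27-loss or all K27-gain genes) with a
  two-sample Kolmogorov–Smirnov statistic, directional in the panel's
  direction of interest. Fisher's exact test (log-space hypergeometric
  tails) covers 2×2 classifications such as target × active.
* **Binding sites.** Poisson-background sliding windows (300 bp, step
  w/3, p < 1e−5, ≥8 reads, 100 bp merge), summit = centre of the
  max-count window; targets are genes with a summit within 5 kb of the
  TSS (one-to-many), with a 10 kb gene-span halo as the broader class.
* **MeDIP screen.** Same windowed machinery at ±1 kb; candidates move
  from <2 RPM to >4 RPM between conditions.

## Worked example

```r
library(episwitch)

# simulate a reference bundle with planted ground truth
bundle <- simulate_bundle(sim_params(), seed = 1)

# run the full pipeline
report <- run_pipeline(bundle)
report
#> RunReport: 2000 genes
#> category counts:
#>
#>    Bi_to_K4   gain_only   K27_to_K4   K4_to_K27   loss_only none_to_K27
#>         116          50          28           9         140         183
#>       other      stable
#>          12        1462
#> sites: 110 (91% within gene halo, 91% within TSS radius)
#> MeDIP candidates: g0478, g0853, g1881

# which switch categories track expression?
report$enrichment[c("category", "n_subset", "n_background",
                    "D", "p_value", "direction")]
#>      category n_subset n_background       D  p_value direction
#> 1   K27_to_K4       28          284 0.97266 1.18e-22    upward
#> 2    Bi_to_K4      116          284 0.00595 9.95e-01    upward
#> 3   K4_to_K27        9          240 0.74170 2.55e-05  downward
#> 4 none_to_K27      183          240 0.03624 8.88e-01  downward

# binding-target strata by repressive-mark change
report$target_strata[c("stratum", "n_subset", "D", "p_value", "direction")]
#>    stratum n_subset     D  p_value direction
#> 1 increase       16 0.438 3.40e-03  downward
#> 2     none       75 0.111 5.22e-01    upward
#> 3 decrease       21 0.641 2.95e-07    upward
```

Reading the output: of 284 genes losing the repressive mark, the 28 that
simultaneously gained the active mark are massively enriched among
upregulated genes (D = 0.97, p ≈ 1e−22), while the 116 bivalent promoters
that merely resolved show no upward enrichment (p ≈ 0.99) — the planted
coordinated/one-sided contrast. On the gain side, the 9 coordinated
repressions enrich downward (p ≈ 3e−5) and the 183 de novo repressive-mark
genes do not (p ≈ 0.89). Binding-factor targets whose repressive mark rose
by ≥0.4 RPM enrich among repressed genes; those whose mark fell enrich
among induced genes. The three MeDIP candidates are exactly the three
planted hypermethylation events.

Individual stages are exported (`gene_status_rpm()`, `classify_status()`,
`transition_table()`, `fold_change()`, `ks_rank_enrichment()`,
`fisher_exact()`, `call_sites()`, `assign_sites()`, `medip_screen()`,
`tss_metaprofile()`, …) and every table reads/writes plain TSV/BED via
`write_tsv()`, `write_sites_bed()`, `write_bundle()` and friends, so stages
can be run and inspected independently. All thresholds live in
`pipeline_config()`.

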