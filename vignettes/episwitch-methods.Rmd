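---
title: "Methods: TSS-anchored mark quantification, switch calling, and rank enrichment"
author: "episwitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS-anchored mark quantification, switch calling, and rank enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episwitch)
```

# The analysis

`episwitch` implements an integrative promoter epigenome/expression analysis
for two-condition ChIP-seq studies, of the kind used to dissect coordinated
histone-mark switching in oncogene-induced senescence. The pipeline connects
five layers:

1. **Windowed read density.** The level of a mark at a genomic position is
   the number of mapped reads per million uniquely mapped reads (RPM) whose
   5' position falls in a window centred there. A gene's promoter mark level
   is the *maximum* windowed RPM over all integer window centres within a
   flank of its TSS (±2 kb by default).
2. **Status and transition calling.** Hard RPM thresholds classify each
   gene as mark-positive, mark-negative, or indeterminate per condition;
   between-condition transitions (loss, gain) require crossing both
   thresholds. Pairs of mark transitions define the coordinated switch
   categories.
3. **Expression ranking.** Array-style scores are globally normalized
   (per-sample mean fixed at 100), genes are ranked by the fold change
   between a baseline sample and the mean of the condition time points, and
   hard fold cutoffs define differential-expression sets.
4. **Rank enrichment.** A two-sample Kolmogorov–Smirnov statistic asks
   whether a gene category occupies systematically high (upward) or low
   (downward) ranks inside its panel; Fisher's exact test handles 2×2
   cross-classifications such as binding-target status × activity.
5. **Binding sites and MeDIP.** A Poisson-background sliding-window caller
   identifies binding sites, which are assigned to genes by summit-to-TSS
   distance; the same windowed-RPM machinery re-parameterized (±1 kb flank,
   500 bp window) screens MeDIP data for promoter methylation changes.

# The windowed-RPM statistic

For a read set with denominator $N$ (total uniquely mapped reads) and window
width $w$, the density at centre $c$ is

$$\mathrm{RPM}(c) = 10^6 \cdot \frac{\#\{i : p_i \in [c - \lfloor w/2\rfloor,\; c - \lfloor w/2\rfloor + w)\}}{N},$$

where $p_i$ is the 5' mapped position of read $i$ (start for `+` reads, end
− 1 for `-` reads; a `midpoint` counting mode is available). The per-gene
statistic is $\max_c \mathrm{RPM}(c)$ over every integer $c$ within the
flank of the TSS.

Numerical choices:

* **Half-open windows.** $[c - \lfloor w/2\rfloor, c - \lfloor w/2\rfloor + w)$
  partitions the genome without ties; for odd $w$ the extra base lies
  downstream. In the aggregate TSS metaprofile the window is defined in
  *transcription coordinates*, which mirrors the interval for minus-strand
  genes and makes the profile exactly strand-symmetric.
* **Exact maximization.** The per-gene maximum is computed by an interval
  sweep over read-induced breakpoints (each read covers a window-width
  interval of centres), not a coarse grid: downstream status calls sit
  directly on this statistic, so it must be deterministic and exact. The
  test suite checks it against a naive all-centres evaluation.
* **No fragment extension or shift.** Reads are counted at their 5' mapped
  base. For short single-end reads and promoter-scale windows this is the
  simplest defensible convention; the counting mode is recorded in the
  configuration.

# Thresholds and the per-million denominator

Default thresholds are the conventional values for tracks of roughly $10^7$
uniquely mapped reads: active mark (H3K4me3, 300 bp windows) positive above
4 RPM and negative below 3; repressive mark (H3K27me3, 500 bp windows)
positive above 1.5 and negative below 1; a continuous repressive-mark change
of at least 0.4 RPM defines increase/decrease strata; the MeDIP screen keeps
genes moving from below 2 RPM to above 4 RPM (±1 kb flank).

Two points deserve emphasis:

* **Absolute RPM thresholds are depth-relative.** An RPM cutoff derived at
  ~$10^7$ mapped reads is only meaningful at a comparable denominator. The
  denominator is therefore an explicit field of the read-set container
  (which may exceed the number of stored reads, e.g. after subsetting reads
  to TSS neighbourhoods), and the synthetic generator defaults to
  $N = 10^7$ per track with background density 0.004 reads/bp — the density
  of such a library spread over a mammalian-scale genome.
* **Gain is the mirror of loss.** A repressive-mark gain requires
  $\mathrm{RPM}_A < 1$ and $\mathrm{RPM}_B > 1.5$, the exact mirror image of
  the loss rule ($> 1.5$ then $< 1$). Genes indeterminate for a needed mark
  in either condition are excluded from the switch categories into an
  explicit residual bucket, never silently dropped; the categories always
  partition the gene set.

# Directional rank-enrichment tests

The enrichment statistic is the two-sample KS distance between the ranks of
a category and the ranks of its complement inside a panel background, with
the small-sample-corrected asymptotic tail
($\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})D$, $n_e = n_1 n_2/(n_1+n_2)$).
`ks_rank_enrichment()` defaults to the two-sided p-value and reports the
direction (upward/downward by mean normalized rank) separately; a
permutation mode (exact enumeration of subset placements when feasible,
Monte-Carlo otherwise) provides a distribution-free alternative.

The category report (`transition_expression_report()`), however, tests each
switch category **one-sided in its panel's direction of interest**: loss
panel categories for upward enrichment, gain-panel categories for downward.
This is a deliberate design choice. The loss panel's background contains the
coordinated-activation genes themselves; when those genes carry strong
induction, any flat category in the same panel is mechanically shifted
*down* relative to its complement, and a two-sided test would "detect" that
shift. The scientific question is whether a category is enriched in its
panel's direction, and the directional tail answers exactly that: a
no-effect category lands near $p = 1$ rather than rejecting on the panel's
own signal. The one-sided tail is well calibrated under uniform subset
placement (rejection rate ≈ 0.05 at $\alpha = 0.05$ in the suite's
2,000-replicate null simulation).

No multiple-testing correction is applied — the report carries raw p-values
and records the number of tests run. Fisher's exact test defaults to the
one-sided (greater) tail for enrichment claims, accumulates hypergeometric
terms in log space so extreme tails remain representable, and is checked in
the suite against full enumeration on all small-margin tables.

# The binding-site caller

No part of the site-calling algorithm is canonical, so it is deliberately
plain and fully config-exposed: windows of 300 bp slide at one-third-window
steps; a window is significant when its read count has Poisson upper-tail
$p < 10^{-5}$ under the genome-wide rate $\lambda = n_\mathrm{reads} \cdot
w / L$ *and* at least 8 reads; significant windows within 100 bp merge into
a site whose summit is the centre of its maximum-count window (leftmost on
ties) and whose score is the summit RPM. Assignment is one-to-many: every
gene with a site summit within 5 kb of its TSS is a target, so one site
between two close promoters marks both genes; a 10 kb halo around the gene
span defines the broader proximity class. Signed distances are positive
downstream of the TSS in transcription direction, with nearest-gene ties
broken lexicographically so re-runs are byte-identical.

# What the synthetic generator emulates

The generator (`simulate_bundle()`) produces annotation, read tracks,
expression, and a truth table under the package's reference conditions:

* 2 chromosomes × 40 Mb, 2,000 genes of 2–10 kb placed uniformly without
  overlap (lengths drawn, gaps distributed by stick-breaking). This is
  ~3× denser than a mammalian genome; at much higher densities,
  read bleed between neighbouring promoters starts to blur planted
  statuses, which is itself realistic but complicates ground-truth scoring.
* Mark reads: uniform background (0.004 reads/bp) plus, per mark-positive
  gene, Poisson-budget clusters of 5' positions at TSS + Normal offsets in
  transcription direction — active mark tight and near (+250 ± 300 bp,
  budget 340), repressive mark wide and further downstream (+500 ± 700 bp,
  budget 180). Budgets put positive genes at ≥3× the positive threshold in
  expectation and leave background maxima well under the negative
  threshold.
* Planted switch categories mirror a realistic two-panel composition
  (30 coordinated-activation, 110 bivalent-resolution and 144 loss-only
  genes in the loss panel; 9 coordinated-repression, 189 de-novo-repressive
  and 41 gain-only in the gain panel, per 2,000 genes). Category counts are
  deterministic roundings of the configured fractions: the smallest
  category (9 genes) must be realized reliably for the panel tests to have
  interpretable power.
* Expression: baseline scores lognormal with class means set by promoter
  state (active ≫ unmarked ≫ repressive-marked); each condition carries one
  per-gene biological-noise draw (sdlog 0.7) plus small per-day jitter, so
  the log fold of an unperturbed gene is symmetric about zero and the
  >5-fold DE rate lands near 5% per side, a realistic array rate.
  Coordinated activation multiplies expression by U(5, 100), coordinated
  repression by U(0.01, 0.2); one-sided switches are planted with
  multiplier 1. With all noise parameters zero the realized fold equals the
  planted multiplier exactly.
* Binding-factor track: per-target clusters (Poisson(30) reads, ±40 bp) at
  TSS + U(−5, +5) kb, decoy clusters far from genes, and a stimulation
  time course in which targets are induced U(8, 30)-fold at 3–6 h over a
  wide (sdlog 2.2) baseline — yielding roughly 80% active targets versus
  30% active non-targets at the score-25 activity cutoff. Targets in the
  repressive-mark increase/decrease strata are drawn from the gain-only /
  loss-only categories and planted repressed / induced, coupling the strata
  to expression.
* MeDIP: a methylated-in-both fraction (25%) plus exactly 3 planted
  hypermethylation genes (background in condition A, cluster in B).

Per-track random streams are seeded from the master seed and a polynomial
hash of the track label, so adding a track never perturbs the others, and a
bundle is bit-reproducible from `(params, seed)`.

**What it does not emulate:** sequence content (no FASTA, no motifs),
mappability or GC bias, fragment-length effects, replicate or batch
structure, input/control tracks, overlapping or alternative TSSs, and the
correlated biology of real transcriptomes (expression noise is independent
across genes). Passing the planted-truth suite therefore demonstrates that
the *computational* chain recovers the structure it assumes, at realistic
depths and effect sizes — not that the thresholds are optimal for any
particular real dataset.

# Problem sizes and numerical tolerances

The test suite exercises the reference conditions at full scale (2,000
genes, ~10^5.5 stored reads per track, one full bundle plus twenty
histone-only replicates for the panel contrast) and smaller instances (200
genes) for module-level properties; these sizes keep a complete run
comfortably fast while leaving planted categories large enough for their
tests to be sharp. The aggregate-profile peak is estimated on a 25 bp grid:
at the reference depth the profile is flat to within counting noise across
±10 bp of its peak, so a 10 bp grid (the display default) cannot localize
the argmax to one step, while 25 bp matches localization power to depth.
Real-valued round-trips are exact to 1e-9; integer statistics (window
counts, ranks, category counts) are exact.

# Known limitations

* Hard thresholds make status calls near the cutoffs depth-sensitive;
  there is no shrinkage or FDR machinery, faithfully to the analysis this
  package reproduces.
* The site caller has no control-track subtraction and assumes a
  homogeneous background rate per genome.
* One TSS per gene: alternative promoters must be pre-collapsed.
* The per-million denominator is taken from the input (or the record count)
  and is not re-estimated; whether unplaced-contig reads belong in it is
  the caller's decision and is recorded in the output provenance.
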