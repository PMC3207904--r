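# Binding-site calling against a Poisson background, distance-based
# assignment of sites to genes, and integration of the target set with
# activity/expression and with H3K27me3 change strata.

#' Call binding sites from ChIP reads with a Poisson background model
#'
#' Slides a window along each chromosome at `step = window/3`; a window is
#' significant when its 5'-position read count has Poisson upper-tail
#' p < `p_cutoff` under the genome-wide background rate
#' `lambda = n_reads * window / genome_length` and the count is at least
#' `min_reads`. Significant windows separated by at most `merge_gap` bp are
#' merged into one site; the summit is the centre of the maximum-count window
#' inside the site (leftmost on ties) and the site score is the summit
#' window's RPM.
#'
#' @param readset a [mapped_read_set()] (non-empty).
#' @param window window width in bp (default 300).
#' @param p_cutoff Poisson upper-tail cutoff (default 1e-5).
#' @param min_reads minimum window read count (default 8).
#' @param merge_gap maximum gap between merged windows in bp (default 100).
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   maximum read end per chromosome.
#' @param mode read-counting mode, see [read_positions()].
#' @return data.frame (`chrom`, `start`, `end`, `summit`, `score`,
#'   `n_reads`), 0-based half-open.
#' @export
call_sites <- function(readset, window = 300, p_cutoff = 1e-5, min_reads = 8,
                       merge_gap = 100, chrom_lengths = NULL,
                       mode = c("5prime", "midpoint")) {
  mode <- match.arg(mode)
  if (nrow(readset$reads) == 0) stop("empty read set", call. = FALSE)
  bychrom <- split_positions(readset, mode)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(readset$reads$end, readset$reads$chrom),
                            max, numeric(1))
  }
  genome_length <- sum(chrom_lengths)
  if (genome_length <= 0) stop("zero genome length", call. = FALSE)
  n_reads_total <- nrow(readset$reads)
  lambda <- n_reads_total * window / genome_length
  step <- max(1L, as.integer(floor(window / 3)))
  fl <- floor(window / 2)
  out <- list()
  for (chrom in names(bychrom)) {
    len <- chrom_lengths[[chrom]]
    if (is.null(len) || is.na(len) || len < window) next
    pos <- bychrom[[chrom]]
    starts <- seq(0, len - window, by = step)
    cnt <- findInterval(starts + window - 1, pos) -
      findInterval(starts - 1, pos)
    pv <- ppois(cnt - 1, lambda, lower.tail = FALSE)
    sig <- which(pv < p_cutoff & cnt >= min_reads)
    if (length(sig) == 0) next
    ir <- IRanges::IRanges(start = starts[sig] + 1, width = window)
    merged <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1)
    for (j in seq_along(merged)) {
      s0 <- IRanges::start(merged)[j] - 1    # back to 0-based
      e0 <- IRanges::end(merged)[j]
      inside <- which(starts >= s0 & starts + window <= e0)
      best <- inside[which.max(cnt[inside])]  # leftmost max (which.max ties)
      summit <- starts[best] + fl
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = s0, end = e0, summit = summit,
        score = 1e6 * cnt[best] / readset$total_mapped,
        n_reads = count_in(pos, s0, e0))
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), summit = numeric(0),
                      score = numeric(0), n_reads = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign binding sites to genes by distance
#'
#' A site is `within_10kb_gene` when its summit falls inside any gene span
#' extended by `gene_halo` on both sides, and `within_5kb_tss` when the
#' summit lies within `tss_radius` of any TSS (absolute distance).
#' Assignment is one-to-many at the gene level: every gene with a site
#' within `tss_radius` of its TSS is a target, so one site between two close
#' TSSs marks both genes. The per-site nearest gene is by absolute
#' summit-to-TSS distance with ties broken to the lexicographically smaller
#' gene id; the signed distance is positive downstream of the TSS in
#' transcription direction.
#'
#' @param sites data.frame from [call_sites()].
#' @param annotation a [gene_annotation()] (non-empty).
#' @param tss_radius TSS distance cutoff in bp (default 5000).
#' @param gene_halo gene-span halo in bp (default 10000).
#' @return list with `sites` (per-site table: `site_id`, `chrom`, `summit`,
#'   `nearest_gene`, `distance`, `within_5kb_tss`, `within_10kb_gene`) and
#'   `genes` (per-gene table: `gene_id`, `is_target`, `n_sites`).
#' @export
assign_sites <- function(sites, annotation, tss_radius = 5000,
                         gene_halo = 10000) {
  if (nrow(annotation) == 0) stop("empty annotation", call. = FALSE)
  n_sites <- nrow(sites)
  per_site <- data.frame(site_id = if (n_sites) sprintf("site_%d", seq_len(n_sites)) else character(0),
                         chrom = sites$chrom, summit = sites$summit,
                         nearest_gene = rep(NA_character_, n_sites),
                         distance = rep(NA_real_, n_sites),
                         within_5kb_tss = logical(n_sites),
                         within_10kb_gene = logical(n_sites))
  genes <- data.frame(gene_id = annotation$gene_id,
                      is_target = FALSE,
                      n_sites = 0L)
  if (n_sites > 0) {
    summits <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$summit + 1, width = 1))
    halo <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(pmax(annotation$start - gene_halo, 0) + 1,
                       annotation$end + gene_halo))
    tssr <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(pmax(annotation$tss - tss_radius, 0) + 1,
                       annotation$tss + tss_radius + 1))
    per_site$within_10kb_gene <-
      IRanges::overlapsAny(summits, halo)
    hits <- GenomicRanges::findOverlaps(summits, tssr)
    per_site$within_5kb_tss <-
      seq_len(n_sites) %in% S4Vectors::queryHits(hits)
    tab <- table(S4Vectors::subjectHits(hits))
    genes$n_sites[as.integer(names(tab))] <- as.integer(tab)
    genes$is_target <- genes$n_sites > 0L
    # deterministic nearest gene (absolute TSS distance, ties by gene_id)
    ann_bychrom <- split(annotation, annotation$chrom)
    for (i in seq_len(n_sites)) {
      ann <- ann_bychrom[[sites$chrom[i]]]
      if (is.null(ann) || nrow(ann) == 0) next
      d <- abs(sites$summit[i] - ann$tss)
      k <- order(d, ann$gene_id)[1]
      per_site$nearest_gene[i] <- ann$gene_id[k]
      sign <- if (ann$strand[k] == "+") 1 else -1
      per_site$distance[i] <- (sites$summit[i] - ann$tss[k]) * sign
    }
  }
  list(sites = per_site, genes = genes)
}

#' Enrichment of binding-site targets in active and upregulated genes
#'
#' Two tests on a shared gene universe: a one-sided Fisher exact test of the
#' 2x2 cross-classification target-status x activity, and a KS rank
#' enrichment of targets within the active genes ranked by stimulation fold
#' change (tested for upward enrichment).
#'
#' @param targets character vector of target gene ids.
#' @param active,inactive character vectors partitioning the universe.
#' @param ranked_active [fold_change()] table restricted to the active genes.
#' @param sided KS sidedness (default one-sided, upward).
#' @return list with `fisher_p`, `table` (2x2 counts), `ks`
#'   (directional KS result or NULL), `untestable`.
#' @export
target_enrichment <- function(targets, active, inactive, ranked_active,
                              sided = "one") {
  universe <- c(active, inactive)
  targets <- intersect(targets, universe)
  a <- length(intersect(targets, active))
  b <- length(intersect(targets, inactive))
  c_ <- length(setdiff(active, targets))
  d <- length(setdiff(inactive, targets))
  if (length(targets) == 0 || length(targets) == length(universe) ||
      length(active) == 0 || length(inactive) == 0)
    return(list(fisher_p = NA_real_, table = c(a = a, b = b, c = c_, d = d),
                ks = NULL, untestable = TRUE))
  fisher_p <- fisher_exact(a, b, c_, d, sided = "greater")
  sub <- intersect(targets, ranked_active$gene_id)
  ks <- if (length(sub) > 0 && length(sub) < nrow(ranked_active))
    ks_directional(ranked_active, sub, "upward", sided) else NULL
  list(fisher_p = fisher_p, table = c(a = a, b = b, c = c_, d = d),
       ks = ks, untestable = FALSE)
}

#' KS enrichment of target strata defined by H3K27me3 change
#'
#' Splits the target genes into `increase` / `none` / `decrease` strata of
#' the repressive-mark change (RPM delta at the conventional 0.4 cutoff) and
#' tests each stratum for rank enrichment within all targets ranked by
#' senescence fold change: the increase stratum for downward enrichment
#' (repression), the none and decrease strata for upward enrichment.
#'
#' @param targets character vector of target gene ids.
#' @param k27 [mark_status_table()] for the repressive mark across the two
#'   conditions.
#' @param ranked [fold_change()] table (genes beyond the targets are
#'   ignored).
#' @param delta RPM change cutoff (default 0.4).
#' @param sided KS sidedness (default one-sided, directional).
#' @return data.frame with one row per stratum: `stratum`, `n_subset`,
#'   `n_background`, `D`, `p_value`, `direction`, `untestable`.
#' @export
stratify_targets_by_delta_k27 <- function(targets, k27, ranked, delta = 0.4,
                                          sided = "one") {
  k27t <- k27[k27$gene_id %in% targets, , drop = FALSE]
  cls <- delta_mark(k27t$rpm_A, k27t$rpm_B, delta)
  ranked_t <- ranked[ranked$gene_id %in% targets, , drop = FALSE]
  dirs <- c(increase = "downward", none = "upward", decrease = "upward")
  rows <- lapply(names(dirs), function(st) {
    sub <- intersect(k27t$gene_id[cls == st], ranked_t$gene_id)
    out <- data.frame(stratum = st, n_subset = length(sub),
                      n_background = nrow(ranked_t), D = NA_real_,
                      p_value = NA_real_, direction = dirs[[st]],
                      untestable = TRUE)
    if (length(sub) > 0 && length(sub) < nrow(ranked_t)) {
      res <- ks_directional(ranked_t, sub, dirs[[st]], sided)
      out$D <- res$D; out$p_value <- res$p_value; out$untestable <- FALSE
    }
    out
  })
  do.call(rbind, rows)
}
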