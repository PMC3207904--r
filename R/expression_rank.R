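# Expression normalization, fold-change ranking, and derived gene sets.

#' Global normalization of an expression matrix
#'
#' Scales each sample (column) so its mean score equals `target` (the
#' conventional array global normalization; target 100 by default).
#' Idempotent; fold rankings are invariant under it when it is applied
#' uniformly.
#'
#' @param mat genes-by-samples non-negative matrix.
#' @param target desired per-sample mean (default 100).
#' @return matrix of the same shape.
#' @export
normalize_global <- function(mat, target = 100) {
  mu <- colMeans(mat)
  if (any(mu <= 0))
    stop(sprintf("sample '%s' has no positive scores",
                 colnames(mat)[which(mu <= 0)[1]]), call. = FALSE)
  sweep(mat, 2, target / mu, "*")
}

#' Fold-change table between a baseline sample and a condition mean
#'
#' `fold = max(mean(condition scores), floor) / max(baseline score, floor)`;
#' the floor (default 1) engages symmetrically so near-zero baselines cannot
#' produce unbounded folds. Genes are ranked by descending fold with ties
#' broken by gene id (stable, documented), rank 1 = most upregulated.
#'
#' @param mat genes-by-samples matrix.
#' @param baseline baseline sample id (single column).
#' @param condition character vector of condition sample ids, averaged.
#' @param floor positive score floor (default 1).
#' @return data.frame (`gene_id`, `baseline`, `condition_mean`, `fold`,
#'   `rank`) sorted by rank.
#' @export
fold_change <- function(mat, baseline, condition, floor = 1) {
  stopifnot(floor > 0)
  missing <- setdiff(c(baseline, condition), colnames(mat))
  if (length(missing))
    stop(sprintf("unknown sample id '%s'", missing[1]), call. = FALSE)
  base <- mat[, baseline]
  cond <- rowMeans(mat[, condition, drop = FALSE])
  fold <- pmax(cond, floor) / pmax(base, floor)
  gene_id <- rownames(mat)
  ord <- order(-fold, gene_id)
  out <- data.frame(gene_id = gene_id[ord],
                    baseline = unname(base[ord]),
                    condition_mean = unname(cond[ord]),
                    fold = unname(fold[ord]),
                    rank = seq_along(ord))
  rownames(out) <- NULL
  out
}

#' Differential-expression gene sets from a fold-change table
#'
#' Strict inequalities: up when `fold > cutoff`, down when
#' `fold < 1/cutoff`.
#'
#' @param fc a [fold_change()] table.
#' @param cutoff fold cutoff (> 1; default 5).
#' @return list with character vectors `up` and `down`.
#' @export
de_sets <- function(fc, cutoff = 5) {
  stopifnot(cutoff > 1)
  list(up = fc$gene_id[fc$fold > cutoff],
       down = fc$gene_id[fc$fold < 1 / cutoff])
}

#' Active genes over a time course
#'
#' A gene is active when its maximum score across the named samples exceeds
#' `score_cutoff` (default 25, the conventional array-score activity floor).
#'
#' @param mat genes-by-samples matrix.
#' @param samples time-course sample ids (non-empty).
#' @param score_cutoff activity cutoff (default 25).
#' @return list with character vectors `active` and `inactive`.
#' @export
active_genes <- function(mat, samples, score_cutoff = 25) {
  if (length(samples) == 0) stop("empty sample list", call. = FALSE)
  missing <- setdiff(samples, colnames(mat))
  if (length(missing))
    stop(sprintf("unknown sample id '%s'", missing[1]), call. = FALSE)
  mx <- apply(mat[, samples, drop = FALSE], 1, max)
  list(active = rownames(mat)[mx > score_cutoff],
       inactive = rownames(mat)[mx <= score_cutoff])
}
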