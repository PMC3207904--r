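# Rank-enrichment (two-sample Kolmogorov-Smirnov) and contingency (Fisher)
# statistics connecting mark transitions and binding-site targets to the
# expression fold-change ranking.

# D+ = sup(F_subset - F_complement), D- = sup(F_complement - F_subset),
# computed over the shared rank ordering (rank 1 = most upregulated, so a
# subset concentrated at small ranks has large D+ = upward enrichment).
ks_rank_D <- function(n, subset_ranks) {
  x <- integer(n)
  x[subset_ranks] <- 1L
  n1 <- length(subset_ranks)
  n2 <- n - n1
  F1 <- cumsum(x) / n1
  F2 <- cumsum(1L - x) / n2
  c(Dplus = max(F1 - F2), Dminus = max(F2 - F1))
}

# Asymptotic tail of the two-sample KS statistic with the small-sample
# correction lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D.
# Two-sided: 2 * sum (-1)^(k-1) exp(-2 k^2 lambda^2); one-sided: exp(-2 lambda^2).
ks_asymptotic_p <- function(D, n1, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * max(D, 0)
  p <- if (sided == "two") {
    k <- seq_len(101)
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  } else {
    exp(-2 * lambda^2)
  }
  min(max(p, 1e-300), 1)
}

#' Kolmogorov-Smirnov rank enrichment of a gene subset
#'
#' Tests whether a subset of genes occupies systematically high (upward) or
#' low (downward) positions in a fold-change-ranked background list, with the
#' two-sample KS statistic between the subset's ranks and the complement's
#' ranks. The reported `direction` is `"upward"` when the subset's mean
#' normalized rank is smaller than the complement's (rank 1 = most
#' upregulated). The p-value is two-sided by default; `sided = "one"` gives
#' the directional tail for `direction`. `method = "permutation"` replaces
#' the asymptotic formula with exact enumeration of subset placements when
#' `choose(n, n1)` is small, else Monte-Carlo resampling.
#'
#' @param ranked a [fold_change()] table restricted to the background set
#'   (or any data.frame with `gene_id` ordered from most up- to most
#'   downregulated).
#' @param subset character vector of gene ids; must be a non-empty proper
#'   subset of the background.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param sided `"two"` (default) or `"one"` (directional).
#' @param n_perm Monte-Carlo permutation count (default 10000).
#' @param max_enum exact-enumeration ceiling on `choose(n, n1)`.
#' @return list of class `EnrichmentResult`: `D`, `p_value`, `direction`,
#'   `method`, `sided`, `n_subset`, `n_background`.
#' @export
ks_rank_enrichment <- function(ranked, subset,
                               method = c("asymptotic", "permutation"),
                               sided = c("two", "one"),
                               n_perm = 10000, max_enum = 25000) {
  method <- match.arg(method)
  sided <- match.arg(sided)
  background <- ranked$gene_id
  n <- length(background)
  if (anyDuplicated(background)) stop("duplicate gene ids in background")
  if (!all(subset %in% background))
    stop("subset is not contained in the background", call. = FALSE)
  n1 <- length(unique(subset))
  if (n1 == 0 || n1 == n)
    stop("degenerate test: subset empty or equal to background",
         call. = FALSE)
  subset_ranks <- which(background %in% subset)
  Ds <- ks_rank_D(n, subset_ranks)
  mean_norm <- mean(subset_ranks) / n
  comp_norm <- mean(setdiff(seq_len(n), subset_ranks)) / n
  direction <- if (mean_norm <= comp_norm) "upward" else "downward"
  D <- if (sided == "two") max(Ds) else
    if (direction == "upward") Ds[["Dplus"]] else Ds[["Dminus"]]
  n2 <- n - n1
  if (method == "asymptotic") {
    p <- ks_asymptotic_p(D, n1, n2, sided)
  } else {
    stat <- function(ranks) {
      d <- ks_rank_D(n, ranks)
      if (sided == "two") max(d) else
        if (direction == "upward") d[["Dplus"]] else d[["Dminus"]]
    }
    if (choose(n, n1) <= max_enum) {
      combs <- utils::combn(n, n1)
      perm <- apply(combs, 2, stat)
      p <- mean(perm >= D - 1e-12)
    } else {
      perm <- vapply(seq_len(n_perm),
                     function(i) stat(sort(sample.int(n, n1))), numeric(1))
      p <- (1 + sum(perm >= D - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(D = unname(D), p_value = p, direction = direction,
                 method = method, sided = sided,
                 n_subset = n1, n_background = n),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("KS rank enrichment: D = %.4f, p = %.3g (%s, %s-sided), %s; subset %d of %d\n",
              x$D, x$p_value, x$method, x$sided, x$direction,
              x$n_subset, x$n_background))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Hypergeometric tail probabilities accumulated in log space, so p-values
#' down to the smallest representable doubles survive. `sided = "greater"`
#' is the enrichment tail P(X >= a) under fixed margins; `sided = "two"`
#' sums all tables with point probability not exceeding the observed one.
#'
#' @param a,b,c,d non-negative counts: `a` = subset with property,
#'   `b` = subset without, `c` = non-subset with, `d` = non-subset without.
#' @param sided `"greater"` (default) or `"two"`.
#' @return p-value.
#' @export
fisher_exact <- function(a, b, c, d, sided = c("greater", "two")) {
  sided <- match.arg(sided)
  if (any(c(a, b, c, d) < 0)) stop("negative counts", call. = FALSE)
  m <- a + c          # property-positive margin
  nn <- b + d         # property-negative margin
  k <- a + b          # subset margin
  if (m + nn == 0 || k == 0 || k == m + nn || m == 0 || nn == 0)
    stop("degenerate margins", call. = FALSE)
  support <- max(0, k - nn):min(k, m)
  logp <- dhyper(support, m, nn, k, log = TRUE)
  if (sided == "greater") {
    sel <- support >= a
  } else {
    obs <- dhyper(a, m, nn, k, log = TRUE)
    sel <- logp <= obs + 1e-7
  }
  # log-sum-exp over the selected part of the support
  lp <- logp[sel]
  mx <- max(lp)
  min(exp(mx + log(sum(exp(lp - mx)))), 1)
}

#' Enrichment report for the coordinated switch categories
#'
#' Reproduces the panel-style integrated analysis: categories of K27 loss
#' (`K27_to_K4`, `Bi_to_K4`) are tested within the background of all genes
#' whose K27 transition is a loss, and categories of K27 gain (`K4_to_K27`,
#' `none_to_K27`) within all K27-gain genes; each test asks for enrichment in
#' the panel's direction of interest (upward for the loss panel, downward for
#' the gain panel) with the one-sided KS tail, which is what makes a
#' no-effect category land near p = 1 rather than rejecting on the panel's
#' own planted signal. Genes absent from the fold-change table are dropped
#' from the backgrounds; an empty or degenerate category is flagged
#' untestable instead of raising.
#'
#' @param transitions a [transition_table()].
#' @param ranked a [fold_change()] table (full gene universe).
#' @param sided KS sidedness for the category tests (default `"one"`).
#' @return data.frame with one row per category: `category`, `panel`,
#'   `n_subset`, `n_background`, `D`, `p_value`, `direction`, `untestable`.
#' @export
transition_expression_report <- function(transitions, ranked, sided = "one") {
  panels <- list(
    K27_to_K4 = list(panel = "K27_loss", dir = "upward"),
    Bi_to_K4 = list(panel = "K27_loss", dir = "upward"),
    K4_to_K27 = list(panel = "K27_gain", dir = "downward"),
    none_to_K27 = list(panel = "K27_gain", dir = "downward"))
  bg_ids <- list(
    K27_loss = transitions$gene_id[transitions$k27_transition == "loss"],
    K27_gain = transitions$gene_id[transitions$k27_transition == "gain"])
  rows <- lapply(names(panels), function(cat) {
    panel <- panels[[cat]]$panel
    want <- panels[[cat]]$dir
    bg <- intersect(ranked$gene_id, bg_ids[[panel]])
    sub <- intersect(transitions$gene_id[transitions$category == cat], bg)
    out <- data.frame(category = cat, panel = panel,
                      n_subset = length(sub), n_background = length(bg),
                      D = NA_real_, p_value = NA_real_,
                      direction = NA_character_, untestable = TRUE)
    if (length(sub) > 0 && length(sub) < length(bg)) {
      ranked_bg <- ranked[ranked$gene_id %in% bg, , drop = FALSE]
      res <- ks_directional(ranked_bg, sub, want, sided)
      out$D <- res$D; out$p_value <- res$p_value
      out$direction <- res$direction; out$untestable <- FALSE
    }
    out
  })
  do.call(rbind, rows)
}

# KS test with the tail taken in a prescribed direction (not the observed
# one), so "no enrichment upward" can score p near 1.
ks_directional <- function(ranked, subset, want = c("upward", "downward"),
                           sided = "one") {
  want <- match.arg(want)
  background <- ranked$gene_id
  n <- length(background)
  subset_ranks <- which(background %in% subset)
  n1 <- length(subset_ranks); n2 <- n - n1
  Ds <- ks_rank_D(n, subset_ranks)
  if (sided == "two") {
    D <- max(Ds)
    p <- ks_asymptotic_p(D, n1, n2, "two")
  } else {
    D <- if (want == "upward") Ds[["Dplus"]] else Ds[["Dminus"]]
    p <- ks_asymptotic_p(D, n1, n2, "one")
  }
  list(D = unname(D), p_value = p, direction = want,
       n_subset = n1, n_background = n)
}
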