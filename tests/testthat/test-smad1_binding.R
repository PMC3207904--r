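test_that("a planted read cluster is called as one site near its centre", {
  set.seed(41)
  bg <- sample(1:1e7, 10000, replace = TRUE)
  cluster <- 5000000 + sample(0:100, 30, replace = TRUE)
  rs <- reads_at(c(bg, cluster), total_mapped = 1e7)
  sites <- call_sites(rs, chrom_lengths = c(chr1 = 1e7))
  expect_equal(nrow(sites), 1)
  expect_lte(abs(sites$summit - 5000050), 150)
  expect_gte(sites$n_reads, 8)

  # two clusters 5 kb apart give two distinct sites
  rs2 <- reads_at(c(bg, cluster, cluster + 5000), total_mapped = 1e7)
  sites2 <- call_sites(rs2, chrom_lengths = c(chr1 = 1e7))
  expect_equal(nrow(sites2), 2)
  expect_true(all(diff(sites2$start) > 100))
})

test_that("uniform background alone yields no sites", {
  set.seed(43)
  rs <- reads_at(sample(1:1e7, 10000, replace = TRUE), total_mapped = 1e7)
  sites <- call_sites(rs, chrom_lengths = c(chr1 = 1e7))
  expect_equal(nrow(sites), 0)
  expect_error(call_sites(rs, chrom_lengths = c(chr1 = 0)), "genome length")
})

test_that("every called site satisfies the calling contract", {
  set.seed(47)
  centers <- seq(2e5, 9.8e6, length.out = 40)
  reads <- c(sample(1:1e7, 20000, replace = TRUE),
             unlist(lapply(centers, function(cc)
               cc + sample(-60:60, 25, replace = TRUE))))
  rs <- reads_at(reads, total_mapped = 1e7)
  sites <- call_sites(rs, chrom_lengths = c(chr1 = 1e7))
  expect_gte(nrow(sites), 35)
  expect_true(all(sites$n_reads >= 8))
  expect_true(all(sites$start <= sites$summit & sites$summit < sites$end))
  expect_true(all(sites$score > 0))
  gaps <- sites$start[-1] - sites$end[-nrow(sites)]
  expect_true(all(gaps > 100))
})

test_that("sites assign to genes by summit distance rules", {
  ann <- gene_annotation(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(100000, 400000), end = c(110000, 410000), strand = c("+", "-")))
  sites <- data.frame(chrom = "chr1",
                      start = c(95000, 116800, 160000),
                      end = c(95400, 117200, 160400),
                      summit = c(95200, 117000, 160200),
                      score = 5, n_reads = 20L)
  asn <- assign_sites(sites, ann)
  # 4.8 kb upstream of gA TSS
  expect_true(asn$sites$within_5kb_tss[1])
  expect_true(asn$sites$within_10kb_gene[1])
  expect_true(asn$genes$is_target[asn$genes$gene_id == "gA"])
  # 7 kb downstream of gA 3' end: in the halo but not the TSS radius
  expect_true(asn$sites$within_10kb_gene[2])
  expect_false(asn$sites$within_5kb_tss[2])
  # 50 kb from everything
  expect_false(asn$sites$within_10kb_gene[3])
  expect_false(asn$sites$within_5kb_tss[3])
  expect_false(asn$genes$is_target[asn$genes$gene_id == "gB"])
  # signed distance: upstream of a plus-strand TSS is negative
  expect_equal(asn$sites$distance[1], -4800)
})

test_that("one site within reach of two TSSs marks both genes", {
  ann <- gene_annotation(data.frame(
    gene_id = c("gB", "gA"), chrom = "chr1",
    start = c(104000, 96000), end = c(112000, 99000), strand = c("+", "-")))
  # summit equidistant (TSS gA at 98999, TSS gB at 104000)
  sites <- data.frame(chrom = "chr1", start = 101300, end = 101700,
                      summit = 101500, score = 5, n_reads = 20L)
  asn <- assign_sites(sites, ann)
  expect_true(all(asn$genes$is_target))
  asn_a <- assign_sites(sites, ann)
  # shuffling annotation row order changes nothing
  asn_b <- assign_sites(sites, ann[2:1, ])
  expect_equal(asn_a$sites$nearest_gene, asn_b$sites$nearest_gene)
  expect_equal(asn_a$genes[order(asn_a$genes$gene_id), ],
               asn_b$genes[order(asn_b$genes$gene_id), ],
               ignore_attr = TRUE)
})

test_that("target activity enrichment detects the planted association", {
  set.seed(53)
  n <- 2000
  ids <- sprintf("g%04d", 1:n)
  targets <- ids[1:200]
  is_active <- c(runif(200) < 0.8, runif(1800) < 0.3)
  active <- ids[is_active]; inactive <- ids[!is_active]
  stim_fold <- rlnorm(n, 0, 1)
  stim_fold[1:200] <- stim_fold[1:200] * 6
  o <- order(-stim_fold, ids)
  ranked_active <- data.frame(gene_id = ids[o], rank = seq_len(n))
  ranked_active <- ranked_active[ranked_active$gene_id %in% active, ]
  res <- target_enrichment(targets, active, inactive, ranked_active)
  expect_false(res$untestable)
  expect_lt(res$fisher_p, 1e-10)
  expect_lt(res$ks$p_value, 1e-6)
  expect_equal(res$ks$direction, "upward")
  # degenerate: everything is a target
  res2 <- target_enrichment(ids, active, inactive, ranked_active)
  expect_true(res2$untestable)
})

test_that("repressive-mark change strata test in their own directions", {
  set.seed(59)
  n <- 150
  ids <- sprintf("g%03d", 1:n)
  rpm_A <- rep(1, n)
  rpm_B <- c(rep(1.8, 20), rep(1.05, 100), rep(0.5, 30))
  k27 <- data.frame(gene_id = ids, rpm_A = rpm_A, rpm_B = rpm_B)
  fold <- c(rlnorm(20, 0, 0.3) * 0.15,    # increase stratum repressed
            rlnorm(100, 0, 0.3),
            rlnorm(30, 0, 0.3) * 6)       # decrease stratum induced
  o <- order(-fold, ids)
  ranked <- data.frame(gene_id = ids[o], rank = seq_len(n))
  strata <- stratify_targets_by_delta_k27(ids, k27, ranked)
  inc <- strata[strata$stratum == "increase", ]
  dec <- strata[strata$stratum == "decrease", ]
  expect_lt(inc$p_value, 0.05); expect_equal(inc$direction, "downward")
  expect_lt(dec$p_value, 0.05); expect_equal(dec$direction, "upward")
  # an empty stratum is flagged untestable
  k27_none <- data.frame(gene_id = ids, rpm_A = 1, rpm_B = 1)
  s2 <- stratify_targets_by_delta_k27(ids, k27_none, ranked)
  expect_true(s2$untestable[s2$stratum == "increase"])
})
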