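test_that("simulated annotation places non-overlapping genes, reproducibly", {
  p <- small_params()
  ann <- simulate_annotation(p, seed = 5)
  expect_equal(nrow(ann), 200)
  expect_true(all(ann$start < ann$end))
  by_chrom <- split(ann, ann$chrom)
  for (a in by_chrom) {
    a <- a[order(a$start), ]
    expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }
  expect_identical(simulate_annotation(p, seed = 5), ann)
  expect_false(identical(simulate_annotation(p, seed = 6)$start, ann$start))
  # infeasible density errors
  expect_error(simulate_annotation(
    sim_params(n_chrom = 1, chrom_length = 1e6, n_genes = 500,
               gene_length_min = 4000, gene_length_max = 6000), 1),
    "infeasible")
})

test_that("planted truth realizes the category and target design", {
  p <- small_params()
  ann <- simulate_annotation(p, 5)
  truth <- plant_transitions(ann, p, 5)
  counts <- table(truth$category)
  expect_equal(unname(counts["K27_to_K4"]), 3)   # round(30/2000 * 200)
  expect_equal(unname(counts["Bi_to_K4"]), 11)
  expect_equal(unname(counts["none_to_K27"]), 19)
  expect_equal(sum(truth$smad1_target), 10)
  expect_equal(sum(truth$medip_class == "hyper"), 3)
  # statuses consistent with categories
  expect_true(all(truth$k27_A[truth$category == "K27_to_K4"] == "plus" &
                    truth$k27_B[truth$category == "K27_to_K4"] == "minus" &
                    truth$k4_A[truth$category == "K27_to_K4"] == "minus" &
                    truth$k4_B[truth$category == "K27_to_K4"] == "plus"))
  # coordinated switches carry effects, one-sided switches do not
  expect_true(all(truth$expr_mult[truth$category == "K27_to_K4"] >= 5))
  expect_true(all(truth$expr_mult[truth$category == "K4_to_K27"] <= 0.2))
  expect_true(all(truth$expr_mult[truth$category == "Bi_to_K4"] == 1))
  # with all fractions zero every gene is stable
  p0 <- small_params(category_fracs = c(K27_to_K4 = 0, Bi_to_K4 = 0,
                                        K4_to_K27 = 0, none_to_K27 = 0,
                                        loss_only = 0, gain_only = 0),
                     target_frac = 0, target_up_frac = 0,
                     target_down_frac = 0)
  t0 <- plant_transitions(simulate_annotation(p0, 1), p0, 1)
  expect_true(all(t0$category == "stable"))
  expect_identical(plant_transitions(ann, p, 5), truth)
})

test_that("mark reads separate planted positive and negative genes", {
  p <- small_params()
  ann <- simulate_annotation(p, 7)
  truth <- plant_transitions(ann, p, 7)
  rs <- simulate_mark_reads(ann, truth, p, "H3K27me3", "A", 7)
  rpm <- gene_status_rpm(rs, ann, 500, 2000)
  th <- default_thresholds("H3K27me3")
  status <- classify_status(rpm$rpm_max, th)
  pos <- truth$k27_A == "plus"
  expect_gte(mean(status[pos] == "plus"), 0.95)
  expect_gte(mean(status[!pos] == "minus"), 0.95)
  # positive genes sit well clear of the threshold on average
  expect_gte(mean(rpm$rpm_max[pos]), 3 * th$hi)

  # zero budget and zero background give an empty read set
  pz <- small_params(k4_budget = 1e-9, background_rate = 0)
  rz <- simulate_mark_reads(ann, truth, pz, "H3K4me3", "A", 7)
  expect_equal(nrow(rz$reads), 0)
})

test_that("bundles are bit-reproducible from the seed", {
  p <- small_params()
  b1 <- simulate_bundle(p, seed = 11)
  b2 <- simulate_bundle(p, seed = 11)
  expect_identical(b1$annotation, b2$annotation)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$expression, b2$expression)
  for (nm in names(b1$reads))
    expect_identical(b1$reads[[nm]]$reads, b2$reads[[nm]]$reads)
  b3 <- simulate_bundle(p, seed = 12)
  expect_false(identical(b1$expression, b3$expression))
})

test_that("expression couples to promoter state as the analysis assumes", {
  p <- sim_params(n_chrom = 1, chrom_length = 3e7, n_genes = 600)
  ann <- simulate_annotation(p, 13)
  truth <- plant_transitions(ann, p, 13)
  mat <- simulate_expression(truth, p, 13)
  base <- mat[, "baseline"]
  k4p <- truth$k4_A == "plus"; k27p <- truth$k27_A == "plus"
  expect_gte(mean(base[k4p]) / mean(base[k27p & !k4p]), 5)
  expect_gt(mean(base[k4p]), mean(base[!k4p]))
  expect_lt(mean(base[k27p]), mean(base[!k27p]))
})

test_that("fold centres on the planted multiplier; exact in the zero-noise limit", {
  p <- small_params(n_genes = 400)
  ann <- simulate_annotation(p, 17)
  truth <- plant_transitions(ann, p, 17)
  mat <- normalize_global(simulate_expression(truth, p, 17))
  fc <- fold_change(mat, "baseline", c("day3", "day7", "day10"))
  flat <- truth$gene_id[truth$expr_mult == 1]
  med <- median(fc$fold[fc$gene_id %in% flat])
  expect_gte(med, 0.8); expect_lte(med, 1.25)

  p0 <- small_params(n_genes = 400, noise_sdlog = 0, day_sdlog = 0)
  t0 <- plant_transitions(ann, p0, 17)
  m0 <- simulate_expression(t0, p0, 17)
  fc0 <- fold_change(m0, "baseline", c("day3", "day7", "day10"),
                     floor = 1e-12)
  merged <- merge(fc0, t0[c("gene_id", "expr_mult")], by = "gene_id")
  expect_equal(merged$fold, merged$expr_mult, tolerance = 1e-9)
})

test_that("binding clusters concentrate at target TSSs with planted decoys", {
  p <- small_params(decoy_frac = 0.2)
  ann <- simulate_annotation(p, 19)
  truth <- plant_transitions(ann, p, 19)
  rs <- simulate_smad1_reads(ann, truth, p, 19)
  sites <- call_sites(rs, chrom_lengths = c(chr1 = p$chrom_length))
  asn <- assign_sites(sites, ann)
  called <- asn$genes$gene_id[asn$genes$is_target]
  planted <- truth$gene_id[truth$smad1_target]
  expect_gte(mean(planted %in% called), 0.9)
  # decoys: sites outside every gene halo, about decoy_frac of the planted count
  n_out <- sum(!asn$sites$within_10kb_gene)
  expect_gte(n_out, 1); expect_lte(n_out, 6)  # Binomial(10, ~0.2) range
})

test_that("coordinated switch sets are recovered at realistic gene spacing", {
  # at ~200 kb per gene, promoter bleed between neighbours is negligible and
  # the planted coordinated categories are recovered nearly exactly
  p <- sim_params(n_genes = 400)
  ann <- simulate_annotation(p, 29)
  tr <- plant_transitions(ann, p, 29)
  status <- function(mark, cond, window) {
    rs <- simulate_mark_reads(ann, tr, p, mark, cond, 29)
    gene_status_rpm(rs, ann, window, 2000)
  }
  k4 <- mark_status_table(status("H3K4me3", "A", 300),
                          status("H3K4me3", "B", 300),
                          default_thresholds("H3K4me3"), "H3K4me3")
  k27 <- mark_status_table(status("H3K27me3", "A", 500),
                           status("H3K27me3", "B", 500),
                           default_thresholds("H3K27me3"), "H3K27me3")
  tt <- transition_table(k4, k27)
  coord <- c("K27_to_K4", "K4_to_K27")
  planted <- tr$gene_id[tr$category %in% coord]
  called <- tt$gene_id[tt$category %in% coord]
  expect_gte(length(planted), 8)
  expect_gte(mean(planted %in% called), 0.95)  # sensitivity
  expect_gte(mean(called %in% planted), 0.95)  # precision
})

test_that("a bundle round-trips through its on-disk representation", {
  p <- small_params(n_genes = 50)
  b <- simulate_bundle(p, seed = 23)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  ann <- read_gene_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$tss[order(ann$gene_id)],
               b$annotation$tss[order(b$annotation$gene_id)])
  mat <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_equal(mat[order(rownames(mat)), ],
               b$expression[order(rownames(b$expression)), ],
               tolerance = 1e-6)
  rs <- read_bed_reads(file.path(dir, "k4_A.bed"),
                       total_mapped = b$reads$k4_A$total_mapped)
  expect_equal(nrow(rs$reads), nrow(b$reads$k4_A$reads))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$seed, 23)
})
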