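# Synthetic input bundles with planted ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# TSS-proximal mark enrichment over a uniform background (active-mark reads
# peaking a few hundred bp downstream of the TSS, the repressive mark wider
# and further downstream), mark/expression coupling (active-mark-positive
# genes expressed high, repressive-mark-positive genes low), planted
# between-condition transitions in which coordinated switches carry
# expression changes while one-sided switches do not, binding-site clusters
# of a stimulated transcription factor near target TSSs, and a MeDIP track
# with a handful of planted promoter hypermethylation events.
#
# Absolute RPM thresholds only transfer across datasets when the per-million
# denominator matches the sequencing depth they were derived at, so each
# track's denominator defaults to 1e7 (a typical uniquely-mapped library)
# while only the reads on the simulated chromosomes are stored; the
# background density (reads per bp) matches a ~1e7-read library spread over
# a mammalian genome.

#' Simulation parameters
#'
#' Defaults define the package's reference study conditions: 2 chromosomes
#' of 20 Mb, 2,000 genes of 2-10 kb, per-track denominator 1e7, background
#' density 0.004 reads/bp (0.002 for the binding-factor track), planted
#' category counts mirroring a two-panel switch analysis
#' (30 coordinated-activation, 110 bivalent-resolution, 9
#' coordinated-repression, 189 de-novo-repressive, 144 loss-only, 41
#' gain-only per 2,000 genes), and effect sizes under which coordinated
#' switches carry strong expression changes while one-sided switches do not.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes.
#' @param gene_length_min,gene_length_max gene span bounds in bp.
#' @param total_mapped per-track per-million denominator.
#' @param background_rate uniform background density, reads per bp
#'   (histone/MeDIP tracks).
#' @param smad1_background_rate background density of the binding-factor
#'   track.
#' @param k4_budget,k27_budget,medip_budget expected planted reads per
#'   mark-positive (or methylated) gene.
#' @param k4_offset_mean,k4_offset_sd,k27_offset_mean,k27_offset_sd,medip_offset_mean,medip_offset_sd
#'   normal offset distribution of planted 5' positions downstream of the
#'   TSS (transcription direction), in bp; the repressive mark is wider than
#'   the active one.
#' @param category_fracs named fractions of genes planted per transition
#'   category (of `n_genes`; realized counts are deterministic roundings).
#' @param base_fracs named fractions splitting the remaining stable genes
#'   into `active`, `repressed`, `bivalent` promoter states (rest unmarked).
#' @param up_mult_range,down_mult_range expression multiplier ranges for the
#'   coordinated activation / repression categories.
#' @param class_meanlog named log-scale baseline expression means for the
#'   four promoter states; `class_sdlog` their spread.
#' @param noise_sdlog per-gene, per-condition lognormal biological noise;
#'   the log fold of an unperturbed gene is N(0, sqrt(2) * noise_sdlog), so
#'   the default 0.7 puts ~5% of stable genes past 5-fold, a realistic array
#'   DE rate; `day_sdlog` extra per-timepoint noise.
#' @param target_frac fraction of genes that are binding-factor targets;
#'   `target_up_frac`/`target_down_frac` the fractions of targets drawn from
#'   the gain-only / loss-only categories (repressive-mark increase and
#'   decrease strata).
#' @param cluster_budget,cluster_sd expected reads and 5'-position spread of
#'   a planted binding cluster; `cluster_offset` the cluster-centre range
#'   around the TSS; `decoy_frac` extra clusters planted >10 kb from genes.
#' @param stim_meanlog,stim_sdlog stimulation-course baseline score
#'   distribution; `stim_noise_sdlog` per-timepoint noise;
#'   `induction_range` target induction multipliers at 3-6 h.
#' @param meth_frac fraction of genes methylated in both conditions;
#'   `n_hyper` planted hypermethylation (low-to-high) genes.
#' @param edge_margin unplaced margin at chromosome ends, bp.
#' @return list of class `SimParams`.
#' @export
sim_params <- function(n_chrom = 2,
                       chrom_length = 4e7,
                       n_genes = 2000,
                       gene_length_min = 2000,
                       gene_length_max = 10000,
                       total_mapped = 1e7,
                       background_rate = 0.004,
                       smad1_background_rate = 0.002,
                       k4_budget = 340,
                       k27_budget = 180,
                       medip_budget = 120,
                       k4_offset_mean = 250, k4_offset_sd = 300,
                       k27_offset_mean = 500, k27_offset_sd = 700,
                       medip_offset_mean = 200, medip_offset_sd = 300,
                       category_fracs = c(K27_to_K4 = 30, Bi_to_K4 = 110,
                                          K4_to_K27 = 9, none_to_K27 = 189,
                                          loss_only = 144,
                                          gain_only = 41) / 2000,
                       base_fracs = c(active = 0.55, repressed = 0.08,
                                      bivalent = 0.04),
                       up_mult_range = c(5, 100),
                       down_mult_range = c(0.01, 0.2),
                       class_meanlog = c(active = log(300),
                                         repressed = log(10),
                                         bivalent = log(30),
                                         none = log(50)),
                       class_sdlog = 0.8,
                       noise_sdlog = 0.7,
                       day_sdlog = 0.1,
                       target_frac = 0.05,
                       target_up_frac = 0.06,
                       target_down_frac = 0.19,
                       cluster_budget = 30,
                       cluster_sd = 40,
                       cluster_offset = 5000,
                       decoy_frac = 0.1,
                       stim_meanlog = log(15),
                       stim_sdlog = 2.2,
                       stim_noise_sdlog = 0.15,
                       induction_range = c(8, 30),
                       meth_frac = 0.25,
                       n_hyper = 3,
                       edge_margin = 10000) {
  p <- as.list(environment())
  stopifnot(sum(p$category_fracs) <= 1, sum(p$base_fracs) <= 1,
            all(unlist(p[c("chrom_length", "n_genes", "total_mapped",
                           "k4_budget", "k27_budget")]) > 0))
  structure(p, class = "SimParams")
}

# deterministic per-track stream: polynomial hash of the label folded into
# the master seed, kept below 2^31 so set.seed() accepts it
track_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer((seed %% 100000) * 20011 + h %% 20011) %% 2147483647L
}

#' Simulate a gene annotation
#'
#' Genes are placed without overlap by drawing lengths uniformly and
#' distributing the remaining chromosome length as random gaps (equivalent
#' to conditioning uniform placement on non-overlap), strands Bernoulli(0.5).
#' Errors if the requested density cannot fit.
#'
#' @param params a [sim_params()].
#' @param seed master seed.
#' @return a [gene_annotation()].
#' @export
simulate_annotation <- function(params = sim_params(), seed = 1) {
  set.seed(track_seed(seed, "annotation"))
  n_per <- diff(round(seq(0, params$n_genes, length.out = params$n_chrom + 1)))
  rows <- list()
  for (ci in seq_len(params$n_chrom)) {
    n <- n_per[ci]
    lens <- round(runif(n, params$gene_length_min, params$gene_length_max))
    free <- params$chrom_length - 2 * params$edge_margin - sum(lens)
    if (free < 0)
      stop("gene density infeasible: total gene length exceeds chromosome",
           call. = FALSE)
    cuts <- sort(runif(n, 0, free))
    starts <- params$edge_margin + round(cuts) +
      c(0, cumsum(lens))[seq_len(n)]
    rows[[ci]] <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n) + sum(n_per[seq_len(ci - 1)])),
      chrom = sprintf("chr%d", ci),
      start = starts, end = starts + lens,
      strand = ifelse(runif(n) < 0.5, "+", "-"))
  }
  gene_annotation(do.call(rbind, rows))
}

#' Plant per-gene ground truth
#'
#' Assigns every gene a transition category (or a stable promoter state), a
#' binding-factor target flag, a repressive-mark change class for targets, a
#' senescence expression multiplier, a stimulation induction multiplier, and
#' a MeDIP methylation class. Coordinated switches (`K27_to_K4`,
#' `K4_to_K27`) carry strong expression multipliers; one-sided switches
#' (`Bi_to_K4`, `none_to_K27`) are planted with multiplier 1. Targets in
#' the repressive-mark increase stratum are drawn from the gain-only
#' category and planted repressed; targets in the decrease stratum from the
#' loss-only category and planted induced; remaining targets come from
#' repressive-mark-negative stable genes.
#'
#' @param annotation a [gene_annotation()].
#' @param params a [sim_params()].
#' @param seed master seed.
#' @return data.frame (`SimulationTruth`): per-gene statuses for both marks
#'   in both conditions, `category`, `smad1_target`, `delta_class`,
#'   `expr_mult`, `stim_mult`, `medip_class`.
#' @export
plant_transitions <- function(annotation, params = sim_params(), seed = 1) {
  set.seed(track_seed(seed, "truth"))
  n <- nrow(annotation)
  counts <- round(params$category_fracs * n)
  if (sum(counts) > n) stop("category fractions exceed 1", call. = FALSE)
  ids <- sample(annotation$gene_id)
  category <- rep("stable", n)
  names(category) <- ids
  at <- 0
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k > 0) category[ids[at + seq_len(k)]] <- cat
    at <- at + k
  }
  stable_ids <- ids[at + seq_len(n - at)]
  bn <- round(params$base_fracs * length(stable_ids))
  base <- rep("none", length(stable_ids))
  names(base) <- stable_ids
  bt <- 0
  for (g in names(bn)) {
    if (bn[[g]] > 0) base[stable_ids[bt + seq_len(bn[[g]])]] <- g
    bt <- bt + bn[[g]]
  }
  category <- category[annotation$gene_id]
  base_group <- rep(NA_character_, n)
  names(base_group) <- names(category)
  base_group[names(base)] <- base
  # mark statuses implied by category / stable state
  k4_A <- k4_B <- k27_A <- k27_B <- rep("minus", n)
  set_state <- function(sel, a4, b4, a27, b27) {
    k4_A[sel] <<- a4; k4_B[sel] <<- b4
    k27_A[sel] <<- a27; k27_B[sel] <<- b27
  }
  set_state(category == "K27_to_K4", "minus", "plus", "plus", "minus")
  set_state(category == "Bi_to_K4", "plus", "plus", "plus", "minus")
  set_state(category == "K4_to_K27", "plus", "minus", "minus", "plus")
  set_state(category == "none_to_K27", "minus", "minus", "minus", "plus")
  set_state(category == "loss_only", "minus", "minus", "plus", "minus")
  set_state(category == "gain_only", "plus", "plus", "minus", "plus")
  st <- category == "stable"
  set_state(st & base_group == "active", "plus", "plus", "minus", "minus")
  set_state(st & base_group == "repressed", "minus", "minus", "plus", "plus")
  set_state(st & base_group == "bivalent", "plus", "plus", "plus", "plus")
  # binding-factor targets and their repressive-mark change strata
  n_targets <- round(params$target_frac * n)
  n_up <- round(params$target_up_frac * n_targets)      # K27 increase
  n_down <- round(params$target_down_frac * n_targets)  # K27 decrease
  pool_up <- sample(annotation$gene_id[category == "gain_only"])
  pool_down <- sample(annotation$gene_id[category == "loss_only"])
  pool_none <- sample(annotation$gene_id[
    st & base_group %in% c("active", "none")])
  if (length(pool_up) < n_up || length(pool_down) < n_down ||
      length(pool_none) < n_targets - n_up - n_down)
    stop("not enough genes to host the requested target strata",
         call. = FALSE)
  t_up <- pool_up[seq_len(n_up)]
  t_down <- pool_down[seq_len(n_down)]
  t_none <- pool_none[seq_len(n_targets - n_up - n_down)]
  smad1_target <- annotation$gene_id %in% c(t_up, t_down, t_none)
  delta_class <- rep("none", n)
  delta_class[annotation$gene_id %in% t_up] <- "increase"
  delta_class[annotation$gene_id %in% t_down] <- "decrease"
  # expression multipliers
  expr_mult <- rep(1, n)
  i_up <- which(category == "K27_to_K4")
  expr_mult[i_up] <- runif(length(i_up), params$up_mult_range[1],
                           params$up_mult_range[2])
  i_dn <- which(category == "K4_to_K27")
  expr_mult[i_dn] <- runif(length(i_dn), params$down_mult_range[1],
                           params$down_mult_range[2])
  i_tu <- which(annotation$gene_id %in% t_up)
  expr_mult[i_tu] <- runif(length(i_tu), 0.05, 0.3)
  i_td <- which(annotation$gene_id %in% t_down)
  expr_mult[i_td] <- runif(length(i_td), 3, 10)
  stim_mult <- rep(1, n)
  stim_mult[smad1_target] <- runif(sum(smad1_target),
                                   params$induction_range[1],
                                   params$induction_range[2])
  # MeDIP classes: methylated-both fraction, plus planted hypermethylation
  medip_class <- ifelse(runif(n) < params$meth_frac, "high", "low")
  hyper_pool <- sample(annotation$gene_id[medip_class == "low" & st &
                                            !smad1_target])
  medip_class[annotation$gene_id %in%
                hyper_pool[seq_len(params$n_hyper)]] <- "hyper"
  data.frame(gene_id = annotation$gene_id,
             base_group = unname(base_group),
             category = unname(category),
             k4_A = k4_A, k4_B = k4_B, k27_A = k27_A, k27_B = k27_B,
             smad1_target = smad1_target,
             delta_class = delta_class,
             expr_mult = expr_mult,
             stim_mult = stim_mult,
             medip_class = medip_class)
}

# shared read emitter: uniform background plus per-positive-gene clusters of
# 5' positions at TSS + Normal(offset) in transcription direction
emit_reads <- function(annotation, positive, budget, offset_mean, offset_sd,
                       params, rate, read_len = 36) {
  chroms <- sprintf("chr%d", seq_len(params$n_chrom))
  bg <- lapply(chroms, function(ch) {
    nb <- rpois(1, rate * params$chrom_length)
    data.frame(chrom = rep(ch, nb),
               pos = floor(runif(nb, read_len, params$chrom_length - read_len)))
  })
  pos_genes <- annotation[annotation$gene_id %in% positive, , drop = FALSE]
  fg <- NULL
  if (nrow(pos_genes) > 0) {
    counts <- rpois(nrow(pos_genes), budget)
    gi <- rep(seq_len(nrow(pos_genes)), counts)
    sign <- ifelse(pos_genes$strand[gi] == "+", 1, -1)
    p <- pos_genes$tss[gi] + sign * round(rnorm(length(gi), offset_mean,
                                                offset_sd))
    p <- pmin(pmax(p, read_len), params$chrom_length - read_len)
    fg <- data.frame(chrom = pos_genes$chrom[gi], pos = p)
  }
  all <- rbind(do.call(rbind, bg), fg)
  minus <- runif(nrow(all)) < 0.5
  data.frame(chrom = all$chrom,
             start = ifelse(minus, all$pos - (read_len - 1), all$pos),
             end = ifelse(minus, all$pos + 1, all$pos + read_len),
             strand = ifelse(minus, "-", "+"))
}

#' Simulate a histone-mark read track
#'
#' Uniform Poisson background over each chromosome plus, for each
#' mark-positive gene, a Poisson(budget) count of reads whose 5' positions
#' fall at TSS + Normal(offset) in transcription direction; the repressive
#' mark uses a wider, further-downstream offset distribution than the active
#' mark.
#'
#' @param annotation a [gene_annotation()].
#' @param truth a [plant_transitions()] table.
#' @param params a [sim_params()].
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @param condition `"A"` or `"B"`.
#' @param seed master seed.
#' @return a [mapped_read_set()].
#' @export
simulate_mark_reads <- function(annotation, truth, params = sim_params(),
                                mark = c("H3K4me3", "H3K27me3"),
                                condition = c("A", "B"), seed = 1) {
  mark <- match.arg(mark); condition <- match.arg(condition)
  label <- paste(mark, condition, sep = "_")
  set.seed(track_seed(seed, label))
  col <- paste0(if (mark == "H3K4me3") "k4_" else "k27_", condition)
  positive <- truth$gene_id[truth[[col]] == "plus"]
  if (mark == "H3K4me3") {
    reads <- emit_reads(annotation, positive, params$k4_budget,
                        params$k4_offset_mean, params$k4_offset_sd,
                        params, params$background_rate)
  } else {
    reads <- emit_reads(annotation, positive, params$k27_budget,
                        params$k27_offset_mean, params$k27_offset_sd,
                        params, params$background_rate)
  }
  mapped_read_set(reads, sample_id = label,
                  total_mapped = max(params$total_mapped, nrow(reads)))
}

#' Simulate a MeDIP read track
#'
#' Methylated promoters (class `high`, plus class `hyper` in condition B
#' only) receive read clusters; everything else is background.
#'
#' @inheritParams simulate_mark_reads
#' @return a [mapped_read_set()].
#' @export
simulate_medip_reads <- function(annotation, truth, params = sim_params(),
                                 condition = c("A", "B"), seed = 1) {
  condition <- match.arg(condition)
  label <- paste("MeDIP", condition, sep = "_")
  set.seed(track_seed(seed, label))
  positive <- truth$gene_id[truth$medip_class == "high" |
                              (truth$medip_class == "hyper" &
                                 condition == "B")]
  reads <- emit_reads(annotation, positive, params$medip_budget,
                      params$medip_offset_mean, params$medip_offset_sd,
                      params, params$background_rate)
  mapped_read_set(reads, sample_id = label,
                  total_mapped = max(params$total_mapped, nrow(reads)))
}

#' Simulate the binding-factor ChIP track
#'
#' Each target gene receives one cluster of Poisson(cluster_budget) reads
#' centred at TSS + U(-cluster_offset, +cluster_offset); a configurable
#' fraction of decoy clusters is placed more than 10 kb away from every gene
#' span; plus uniform background.
#'
#' @inheritParams simulate_mark_reads
#' @return a [mapped_read_set()].
#' @export
simulate_smad1_reads <- function(annotation, truth, params = sim_params(),
                                 seed = 1) {
  set.seed(track_seed(seed, "Smad1"))
  targets <- annotation[annotation$gene_id %in%
                          truth$gene_id[truth$smad1_target], , drop = FALSE]
  read_len <- 36
  rows <- list()
  if (nrow(targets) > 0) {
    centers <- targets$tss + round(runif(nrow(targets),
                                         -params$cluster_offset,
                                         params$cluster_offset))
    counts <- rpois(nrow(targets), params$cluster_budget)
    gi <- rep(seq_len(nrow(targets)), counts)
    rows$target <- data.frame(
      chrom = targets$chrom[gi],
      pos = centers[gi] + round(rnorm(length(gi), 0, params$cluster_sd)))
  }
  n_decoy <- round(params$decoy_frac * nrow(targets))
  if (n_decoy > 0) {
    placed <- 0; dec <- list(); tries <- 0
    while (placed < n_decoy && tries < 20000) {
      tries <- tries + 1
      ch <- sprintf("chr%d", sample.int(params$n_chrom, 1))
      p <- floor(runif(1, 0, params$chrom_length))
      ann <- annotation[annotation$chrom == ch, ]
      d <- pmax(ann$start - p, p - ann$end, 0)
      if (all(d > 10000 + params$cluster_offset / 2)) {
        placed <- placed + 1
        cnt <- rpois(1, params$cluster_budget)
        dec[[placed]] <- data.frame(
          chrom = ch, pos = p + round(rnorm(cnt, 0, params$cluster_sd)))
      }
    }
    rows$decoy <- do.call(rbind, dec)
  }
  bgrate <- params$smad1_background_rate
  bg <- lapply(sprintf("chr%d", seq_len(params$n_chrom)), function(ch) {
    nb <- rpois(1, bgrate * params$chrom_length)
    data.frame(chrom = rep(ch, nb),
               pos = floor(runif(nb, read_len, params$chrom_length - read_len)))
  })
  all <- rbind(do.call(rbind, rows), do.call(rbind, bg))
  all$pos <- pmin(pmax(all$pos, read_len), params$chrom_length - read_len)
  minus <- runif(nrow(all)) < 0.5
  reads <- data.frame(chrom = all$chrom,
                      start = ifelse(minus, all$pos - (read_len - 1), all$pos),
                      end = ifelse(minus, all$pos + 1, all$pos + read_len),
                      strand = ifelse(minus, "-", "+"))
  mapped_read_set(reads, sample_id = "Smad1",
                  total_mapped = max(params$total_mapped, nrow(reads)))
}

#' Simulate the expression matrix
#'
#' Baseline scores are lognormal with class means set by the condition-A
#' promoter state (active high, repressed low); senescence time points
#' (day3/7/10) are baseline x planted multiplier x shared per-gene lognormal
#' noise x small per-day noise; a separate stimulation time course
#' (0/3/6/12/24 h) induces the planted targets at 3-6 h. With all noise
#' sdlogs zero the realized fold equals the planted multiplier exactly.
#'
#' @param truth a [plant_transitions()] table.
#' @param params a [sim_params()].
#' @param seed master seed.
#' @return genes-by-samples matrix with columns `baseline`, `day3`, `day7`,
#'   `day10`, `bmp_0h`, `bmp_3h`, `bmp_6h`, `bmp_12h`, `bmp_24h`.
#' @export
simulate_expression <- function(truth, params = sim_params(), seed = 1) {
  set.seed(track_seed(seed, "expression"))
  n <- nrow(truth)
  state <- ifelse(truth$k4_A == "plus" & truth$k27_A == "plus", "bivalent",
           ifelse(truth$k4_A == "plus", "active",
           ifelse(truth$k27_A == "plus", "repressed", "none")))
  base <- rlnorm(n, params$class_meanlog[state], params$class_sdlog)
  # one biological-noise draw per gene per condition (baseline and senescent)
  # plus small per-day jitter: the log fold is then symmetric around the
  # planted multiplier and per-sample global normalization is fold-neutral,
  # since both conditions carry noise of identical distribution
  noise_base <- rlnorm(n, 0, params$noise_sdlog)
  noise_cond <- rlnorm(n, 0, params$noise_sdlog)
  day <- function() base * truth$expr_mult * noise_cond *
    rlnorm(n, 0, params$day_sdlog)
  stim0 <- rlnorm(n, params$stim_meanlog, params$stim_sdlog)
  snoise <- function() rlnorm(n, 0, params$stim_noise_sdlog)
  mat <- cbind(baseline = base * noise_base,
               day3 = day(), day7 = day(), day10 = day(),
               bmp_0h = stim0 * snoise(),
               bmp_3h = stim0 * truth$stim_mult * snoise(),
               bmp_6h = stim0 * truth$stim_mult * snoise(),
               bmp_12h = stim0 * sqrt(truth$stim_mult) * snoise(),
               bmp_24h = stim0 * snoise())
  rownames(mat) <- truth$gene_id
  mat
}

#' Simulate a complete input bundle
#'
#' @param params a [sim_params()].
#' @param seed master seed; the same seed reproduces the bundle exactly.
#' @return list with `annotation`, `truth`, `reads` (named list of
#'   [mapped_read_set()]s: `k4_A`, `k4_B`, `k27_A`, `k27_B`, `medip_A`,
#'   `medip_B`, `smad1`), `expression`, `params`, `seed`.
#' @export
simulate_bundle <- function(params = sim_params(), seed = 1) {
  annotation <- simulate_annotation(params, seed)
  truth <- plant_transitions(annotation, params, seed)
  reads <- list(
    k4_A = simulate_mark_reads(annotation, truth, params, "H3K4me3", "A", seed),
    k4_B = simulate_mark_reads(annotation, truth, params, "H3K4me3", "B", seed),
    k27_A = simulate_mark_reads(annotation, truth, params, "H3K27me3", "A", seed),
    k27_B = simulate_mark_reads(annotation, truth, params, "H3K27me3", "B", seed),
    medip_A = simulate_medip_reads(annotation, truth, params, "A", seed),
    medip_B = simulate_medip_reads(annotation, truth, params, "B", seed),
    smad1 = simulate_smad1_reads(annotation, truth, params, seed))
  list(annotation = annotation, truth = truth, reads = reads,
       expression = simulate_expression(truth, params, seed),
       params = params, seed = seed)
}

#' Write a simulated bundle to a directory
#'
#' Annotation, truth and expression as TSV, each read track as BED6, plus a
#' YAML manifest of the generative parameters and seed.
#'
#' @param bundle from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- as.data.frame(bundle$annotation)[
    c("gene_id", "chrom", "start", "end", "strand")]
  write_tsv(ann, file.path(dir, "annotation.tsv"))
  write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  write_expression_table(bundle$expression, file.path(dir, "expression.tsv"))
  for (nm in names(bundle$reads)) {
    rs <- bundle$reads[[nm]]
    r <- rs$reads
    bed <- data.frame(r$chrom,
                      format(r$start, scientific = FALSE, trim = TRUE),
                      format(r$end, scientific = FALSE, trim = TRUE),
                      sprintf("r%d", seq_len(nrow(r))), 0, r$strand)
    write.table(bed, file.path(dir, paste0(nm, ".bed")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest <- bundle$params
  manifest$seed <- bundle$seed
  manifest$total_mapped_by_track <-
    lapply(bundle$reads, function(r) r$total_mapped)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
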