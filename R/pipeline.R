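# End-to-end orchestration: one configuration object drives normalization,
# density, status, transitions, ranking, enrichment, binding-site analysis
# and the MeDIP screen, with deterministic outputs.

#' Pipeline configuration
#'
#' Every numeric constant used by the stages lives here; defaults are the
#' conventional values for ~1e7-read tracks (300/500 bp windows, +/-2 kb
#' flank around the TSS and +/-1 kb for MeDIP, mark thresholds 4/3 and
#' 1.5/1 RPM, repressive-mark change cutoff 0.4 RPM, 5-fold DE lists,
#' activity score cutoff 25, 5 kb TSS radius and 10 kb gene halo for target
#' assignment).
#'
#' @param ... overrides of the default keys (unknown keys are an error).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    k4_window = 300, k27_window = 500, medip_window = 500,
    smad1_window = 300,
    flank = 2000, medip_flank = 1000,
    k4_hi = 4, k4_lo = 3, k27_hi = 1.5, k27_lo = 1,
    delta_k27 = 0.4,
    medip_lo = 2, medip_hi = 4,
    norm_target = 100, floor = 1, de_cutoff = 5, active_cutoff = 25,
    baseline_sample = "baseline",
    condition_samples = c("day3", "day7", "day10"),
    stim_baseline = "bmp_0h",
    stim_condition = c("bmp_3h", "bmp_6h"),
    stim_samples = c("bmp_0h", "bmp_3h", "bmp_6h", "bmp_12h", "bmp_24h"),
    smad1_p_cutoff = 1e-5, smad1_min_reads = 8, smad1_merge_gap = 100,
    tss_radius = 5000, gene_halo = 10000,
    read_mode = "5prime",
    ks_sided = "one")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key '%s'", unknown[1]), call. = FALSE)
  cfg[names(over)] <- over
  numeric_keys <- c("k4_window", "k27_window", "medip_window", "smad1_window",
                    "flank", "medip_flank", "k4_hi", "k4_lo", "k27_hi",
                    "k27_lo", "delta_k27", "medip_lo", "medip_hi",
                    "norm_target", "floor", "de_cutoff", "active_cutoff",
                    "smad1_p_cutoff", "smad1_min_reads", "smad1_merge_gap",
                    "tss_radius", "gene_halo")
  bad <- numeric_keys[vapply(cfg[numeric_keys],
                             function(v) !is.numeric(v) || v <= 0,
                             logical(1))]
  if (length(bad))
    stop(sprintf("config key '%s' must be a positive number", bad[1]),
         call. = FALSE)
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Write / read a pipeline configuration
#'
#' Flat YAML key:value representation; round-trips losslessly.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Proximity summary of a target assignment
#'
#' Fractions of sites whose summit falls within the gene halo and within the
#' TSS radius, as exact fractions and display percentages rounded to the
#' nearest integer.
#'
#' @param assignment result of [assign_sites()] (or its `sites` table).
#' @return list: `n_sites`, `n_within_gene`, `n_within_tss`,
#'   `frac_within_gene`, `frac_within_tss`, `pct_within_gene`,
#'   `pct_within_tss`, `untestable`.
#' @export
report_proximity <- function(assignment) {
  sites <- if (is.data.frame(assignment)) assignment else assignment$sites
  n <- nrow(sites)
  if (n == 0)
    return(list(n_sites = 0L, n_within_gene = 0L, n_within_tss = 0L,
                frac_within_gene = NA_real_, frac_within_tss = NA_real_,
                pct_within_gene = NA_real_, pct_within_tss = NA_real_,
                untestable = TRUE))
  ng <- sum(sites$within_10kb_gene)
  nt <- sum(sites$within_5kb_tss)
  list(n_sites = n, n_within_gene = ng, n_within_tss = nt,
       frac_within_gene = ng / n, frac_within_tss = nt / n,
       pct_within_gene = round(100 * ng / n),
       pct_within_tss = round(100 * nt / n),
       untestable = FALSE)
}

#' Run the complete pipeline on an input bundle
#'
#' Executes normalization, per-gene windowed density for both marks in both
#' conditions, status and transition calling, fold-change ranking and DE
#' sets, the category enrichment report, binding-site calling/assignment
#' with activity and change-strata enrichment, and the MeDIP screen.
#' Deterministic: re-running on the same inputs and config reproduces the
#' report exactly.
#'
#' @param bundle list with `annotation`, `expression`, and `reads`
#'   (`k4_A`, `k4_B`, `k27_A`, `k27_B`, optionally `medip_A`, `medip_B`,
#'   `smad1`), e.g. from [simulate_bundle()] or assembled from files.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, every intermediate
#'   table is written as TSV/BED.
#' @return list of class `RunReport` (status tables, transitions, category
#'   counts, fold table, DE sets, enrichment report, sites, assignment,
#'   proximity, target enrichment, strata, MeDIP candidates, config).
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         output_dir = NULL) {
  required <- c("k4_A", "k4_B", "k27_A", "k27_B")
  missing <- setdiff(required, names(bundle$reads))
  if (length(missing))
    stop(sprintf("validation: missing read track '%s'", missing[1]),
         call. = FALSE)
  missing_s <- setdiff(c(config$baseline_sample, config$condition_samples),
                       colnames(bundle$expression))
  if (length(missing_s))
    stop(sprintf("validation: missing expression sample '%s'", missing_s[1]),
         call. = FALSE)
  annotation <- bundle$annotation
  mode <- config$read_mode

  expr <- normalize_global(bundle$expression, config$norm_target)

  dens <- function(track, window, flank)
    gene_status_rpm(bundle$reads[[track]], annotation, window, flank, mode)
  k4 <- mark_status_table(
    dens("k4_A", config$k4_window, config$flank),
    dens("k4_B", config$k4_window, config$flank),
    mark_thresholds(config$k4_hi, config$k4_lo), "H3K4me3")
  k27 <- mark_status_table(
    dens("k27_A", config$k27_window, config$flank),
    dens("k27_B", config$k27_window, config$flank),
    mark_thresholds(config$k27_hi, config$k27_lo), "H3K27me3")
  transitions <- transition_table(k4, k27)

  fc <- fold_change(expr, config$baseline_sample, config$condition_samples,
                    config$floor)
  de <- de_sets(fc, config$de_cutoff)
  enrichment <- transition_expression_report(transitions, fc,
                                             sided = config$ks_sided)

  report <- list(
    n_genes = nrow(annotation),
    k4 = k4, k27 = k27, transitions = transitions,
    category_counts = table(transitions$category),
    fold = fc, de = de, enrichment = enrichment,
    config = config)

  if ("smad1" %in% names(bundle$reads)) {
    sites <- call_sites(bundle$reads$smad1, config$smad1_window,
                        config$smad1_p_cutoff, config$smad1_min_reads,
                        config$smad1_merge_gap,
                        chrom_lengths = bundle$chrom_lengths, mode = mode)
    assignment <- assign_sites(sites, annotation, config$tss_radius,
                               config$gene_halo)
    targets <- assignment$genes$gene_id[assignment$genes$is_target]
    report$sites <- sites
    report$assignment <- assignment
    report$proximity <- report_proximity(assignment)
    stim_ok <- all(c(config$stim_baseline, config$stim_condition,
                     config$stim_samples) %in% colnames(expr))
    if (stim_ok) {
      act <- active_genes(expr, config$stim_samples, config$active_cutoff)
      stim_fc <- fold_change(expr, config$stim_baseline,
                             config$stim_condition, config$floor)
      ranked_active <- stim_fc[stim_fc$gene_id %in% act$active, , drop = FALSE]
      report$active <- act
      report$target_enrichment <- target_enrichment(
        targets, act$active, act$inactive, ranked_active,
        sided = config$ks_sided)
    }
    report$target_strata <- stratify_targets_by_delta_k27(
      targets, k27, fc, config$delta_k27, sided = config$ks_sided)
  }

  if (all(c("medip_A", "medip_B") %in% names(bundle$reads))) {
    mA <- dens("medip_A", config$medip_window, config$medip_flank)
    mB <- dens("medip_B", config$medip_window, config$medip_flank)
    report$medip <- data.frame(gene_id = mA$gene_id, rpm_A = mA$rpm_max,
                               rpm_B = mB$rpm_max)
    report$medip_candidates <- medip_screen(mA, mB, config$medip_lo,
                                            config$medip_hi)
  }

  class(report) <- c("RunReport", "list")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport: %d genes\n", x$n_genes))
  cat("category counts:\n")
  print(x$category_counts)
  if (!is.null(x$proximity) && !x$proximity$untestable)
    cat(sprintf("sites: %d (%d%% within gene halo, %d%% within TSS radius)\n",
                x$proximity$n_sites, x$proximity$pct_within_gene,
                x$proximity$pct_within_tss))
  if (!is.null(x$medip_candidates))
    cat(sprintf("MeDIP candidates: %s\n",
                paste(x$medip_candidates, collapse = ", ")))
  invisible(x)
}

#' Write every report table to a directory
#' @param report a [run_pipeline()] report.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$k4, file.path(dir, "status_H3K4me3.tsv"))
  write_tsv(report$k27, file.path(dir, "status_H3K27me3.tsv"))
  write_tsv(report$transitions, file.path(dir, "transitions.tsv"))
  write_tsv(report$fold, file.path(dir, "fold_change.tsv"))
  write_tsv(report$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(report$sites)) {
    write_sites_bed(report$sites, file.path(dir, "sites.bed"))
    write_tsv(report$assignment$sites, file.path(dir, "site_assignment.tsv"))
    write_tsv(report$assignment$genes, file.path(dir, "target_genes.tsv"))
    write_tsv(report$target_strata, file.path(dir, "target_strata.tsv"))
  }
  if (!is.null(report$medip))
    write_tsv(report$medip, file.path(dir, "medip_status.tsv"))
  write_config(report$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
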