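# Threshold-based mark-status classification, between-condition transition
# calling, and the coordinated switch categories.
#
# Default thresholds are the conventional per-million cutoffs for ~1e7-read
# tracks: H3K4me3 +/- at >4 / <3 RPM (300 bp windows), H3K27me3 +/- at
# >1.5 / <1 RPM (500 bp windows). A gene between the two cutoffs is
# indeterminate and is excluded from transition categories rather than
# silently dropped. H3K27me3 gain is the mirror image of the loss rule
# (rpm_A < lo and rpm_B > hi).

#' Mark status thresholds
#'
#' @param hi RPM above which a gene is mark-positive.
#' @param lo RPM below which a gene is mark-negative (`hi >= lo > 0`).
#' @return list of class `MarkThresholds`.
#' @export
mark_thresholds <- function(hi, lo) {
  stopifnot(hi >= lo, lo > 0)
  structure(list(hi = hi, lo = lo), class = "MarkThresholds")
}

#' Default thresholds for the two histone marks
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @return a [mark_thresholds()] object (4/3 for H3K4me3, 1.5/1 for H3K27me3).
#' @export
default_thresholds <- function(mark = c("H3K4me3", "H3K27me3")) {
  mark <- match.arg(mark)
  if (mark == "H3K4me3") mark_thresholds(4, 3) else mark_thresholds(1.5, 1)
}

#' Classify a windowed RPM value into +/-/indeterminate
#'
#' @param rpm_max per-gene maximum windowed RPM (vectorized).
#' @param th a [mark_thresholds()].
#' @return character vector in `{"plus","minus","indeterminate"}`.
#' @export
classify_status <- function(rpm_max, th) {
  stopifnot(all(rpm_max >= 0))
  ifelse(rpm_max > th$hi, "plus",
         ifelse(rpm_max < th$lo, "minus", "indeterminate"))
}

#' Call a between-condition mark transition
#'
#' Loss requires `rpm_A > hi` and `rpm_B < lo`; gain is the mirror image
#' (`rpm_A < lo`, `rpm_B > hi`); stable means equal, determinate statuses in
#' both conditions; everything else is indeterminate.
#'
#' @param rpm_A,rpm_B per-gene RPM in conditions A and B (vectorized).
#' @param th a [mark_thresholds()].
#' @return character vector in `{"loss","gain","stable","indeterminate"}`.
#' @export
call_transition <- function(rpm_A, rpm_B, th) {
  sA <- classify_status(rpm_A, th)
  sB <- classify_status(rpm_B, th)
  out <- rep("indeterminate", length(sA))
  out[sA == "plus" & sB == "minus"] <- "loss"
  out[sA == "minus" & sB == "plus"] <- "gain"
  out[sA == sB & sA != "indeterminate"] <- "stable"
  out
}

#' Build a per-gene mark status table for one mark across two conditions
#'
#' @param rpm_A,rpm_B data.frames (`gene_id`, `rpm_max`) from
#'   [gene_status_rpm()] for conditions A and B.
#' @param th a [mark_thresholds()].
#' @param mark mark label.
#' @return data.frame (`gene_id`, `mark`, `rpm_A`, `rpm_B`, `status_A`,
#'   `status_B`, `transition`).
#' @export
mark_status_table <- function(rpm_A, rpm_B, th, mark = "mark") {
  stopifnot(identical(rpm_A$gene_id, rpm_B$gene_id))
  data.frame(gene_id = rpm_A$gene_id,
             mark = mark,
             rpm_A = rpm_A$rpm_max,
             rpm_B = rpm_B$rpm_max,
             status_A = classify_status(rpm_A$rpm_max, th),
             status_B = classify_status(rpm_B$rpm_max, th),
             transition = call_transition(rpm_A$rpm_max, rpm_B$rpm_max, th))
}

#' Coordinated switch categories from K4 and K27 statuses
#'
#' Assigns each gene the first matching label in the fixed order
#' `K27_to_K4` (K27 loss and K4 gain), `Bi_to_K4` (K4 plus in both
#' conditions and K27 loss), `K4_to_K27` (K4 loss and K27 gain),
#' `none_to_K27` (K4 minus in both and K27 gain), then `loss_only`,
#' `gain_only`, `stable`, `other`. Genes indeterminate for a needed mark end
#' up in `other`, never silently dropped; the categories partition the gene
#' set.
#'
#' @param k4,k27 status tables from [mark_status_table()] for H3K4me3 and
#'   H3K27me3 on the same genes.
#' @return data.frame (`gene_id`, per-mark statuses/transitions, `category`).
#' @export
transition_table <- function(k4, k27) {
  stopifnot(identical(k4$gene_id, k27$gene_id))
  n <- nrow(k4)
  cat <- rep(NA_character_, n)
  k4t <- k4$transition; k27t <- k27$transition
  pick <- function(cond) is.na(cat) & cond
  cat[pick(k27t == "loss" & k4t == "gain")] <- "K27_to_K4"
  cat[pick(k4$status_A == "plus" & k4$status_B == "plus" &
             k27t == "loss")] <- "Bi_to_K4"
  cat[pick(k4t == "loss" & k27t == "gain")] <- "K4_to_K27"
  cat[pick(k4$status_A == "minus" & k4$status_B == "minus" &
             k27t == "gain")] <- "none_to_K27"
  any_loss <- k4t == "loss" | k27t == "loss"
  any_gain <- k4t == "gain" | k27t == "gain"
  cat[pick(any_loss & !any_gain)] <- "loss_only"
  cat[pick(any_gain & !any_loss)] <- "gain_only"
  cat[pick(k4t == "stable" & k27t == "stable")] <- "stable"
  cat[is.na(cat)] <- "other"
  data.frame(gene_id = k4$gene_id,
             k4_A = k4$status_A, k4_B = k4$status_B,
             k27_A = k27$status_A, k27_B = k27$status_B,
             k4_transition = k4t, k27_transition = k27t,
             delta_k4 = k4$rpm_B - k4$rpm_A,
             delta_k27 = k27$rpm_B - k27$rpm_A,
             category = cat)
}

#' Classify a continuous RPM change
#'
#' @param rpm_A,rpm_B per-gene RPM in the two conditions (vectorized).
#' @param delta minimum absolute change in RPM (default 0.4).
#' @return character vector in `{"increase","decrease","none"}`.
#' @export
delta_mark <- function(rpm_A, rpm_B, delta = 0.4) {
  stopifnot(delta > 0)
  d <- rpm_B - rpm_A
  ifelse(d >= delta, "increase", ifelse(-d >= delta, "decrease", "none"))
}

#' MeDIP promoter hypermethylation screen
#'
#' Returns the genes whose MeDIP windowed RPM rises from below `lo` in the
#' baseline condition to above `hi` in the second condition. Statuses are
#' expected to be computed with the MeDIP geometry (500 bp windows within
#' +/-1 kb of the TSS).
#'
#' @param rpm_A,rpm_B data.frames (`gene_id`, `rpm_max`) for the two
#'   conditions.
#' @param lo baseline ceiling (default 2 RPM).
#' @param hi second-condition floor (default 4 RPM).
#' @return character vector of candidate gene ids.
#' @export
medip_screen <- function(rpm_A, rpm_B, lo = 2, hi = 4) {
  stopifnot(identical(rpm_A$gene_id, rpm_B$gene_id))
  rpm_A$gene_id[rpm_A$rpm_max < lo & rpm_B$rpm_max > hi]
}
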