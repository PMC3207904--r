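# Input/output for every external representation the pipeline touches.
# Coordinates are BED-native 0-based half-open throughout; nothing is shifted
# on the way in or out.

norm_strand <- function(strand, what = "strand") {
  s <- as.character(strand)
  s[s == "−"] <- "-"   # tolerate unicode minus from copy-pasted tables
  bad <- !(s %in% c("+", "-", "."))
  if (any(bad)) {
    stop(sprintf("invalid %s symbol '%s' (expected +, - or .)",
                 what, s[which(bad)[1]]), call. = FALSE)
  }
  if (any(s == ".")) {
    warning("'.' strand treated as '+' (read strand does not affect counting)",
            call. = FALSE)
    s[s == "."] <- "+"
  }
  s
}

#' Construct a mapped read set
#'
#' A `MappedReadSet` holds strand-aware genomic read positions for one sample
#' together with the per-million normalization denominator. `total_mapped`
#' may exceed the number of stored reads (e.g. when only reads near TSSs were
#' retained from a larger library); it is the denominator of every RPM value
#' computed from the set.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open, strand `+`/`-`).
#' @param sample_id character scalar naming the sample/track.
#' @param total_mapped count of uniquely mapped reads used as the per-million
#'   denominator; defaults to `nrow(reads)`.
#' @return An object of class `MappedReadSet`.
#' @export
mapped_read_set <- function(reads, sample_id = "sample",
                            total_mapped = nrow(reads)) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "end", "strand") %in% names(reads)))
  reads$chrom <- as.character(reads$chrom)
  reads$start <- as.numeric(reads$start)
  reads$end <- as.numeric(reads$end)
  if (nrow(reads) > 0 && any(reads$start >= reads$end))
    stop("read with start >= end", call. = FALSE)
  reads$strand <- if (nrow(reads) > 0) norm_strand(reads$strand) else character(0)
  total_mapped <- as.numeric(total_mapped)
  if (length(total_mapped) != 1 || is.na(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be a single positive count", call. = FALSE)
  if (total_mapped < nrow(reads))
    stop("total_mapped cannot be smaller than the number of stored reads",
         call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 reads = reads[c("chrom", "start", "end", "strand")],
                 total_mapped = total_mapped),
            class = "MappedReadSet")
}

#' @export
print.MappedReadSet <- function(x, ...) {
  cat(sprintf("MappedReadSet '%s': %d stored reads on %d chromosome(s), total_mapped = %s\n",
              x$sample_id, nrow(x$reads), length(unique(x$reads$chrom)),
              format(x$total_mapped, big.mark = ",")))
  invisible(x)
}

#' Read mapped reads from a BED file
#'
#' Parses a tab- or whitespace-delimited BED3+ file. When a sixth column is
#' present it is taken as the strand (`.` is stored as `+` with a warning);
#' otherwise all reads are stored as `+`. Records on unknown chromosomes are
#' retained. Coordinates are stored exactly as in the file (0-based
#' half-open).
#'
#' @param path BED file path.
#' @param total_mapped per-million denominator; defaults to the number of
#'   records in the file.
#' @param sample_id sample label, defaults to the file name.
#' @return A [mapped_read_set()].
#' @export
read_bed_reads <- function(path, total_mapped = NULL,
                           sample_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    if (is.null(total_mapped))
      stop("empty BED file and no total_mapped supplied", call. = FALSE)
    return(mapped_read_set(
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), strand = character(0)),
      sample_id = sample_id, total_mapped = total_mapped))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields",
                 which(nf < 3)[1]), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 bad[1]), call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: start >= end", bad[1]),
         call. = FALSE)
  strand <- ifelse(nf >= 6, vapply(fields, function(f)
    if (length(f) >= 6) f[[6]] else "+", ""), "+")
  ok <- strand %in% c("+", "-", ".", "−")
  if (!all(ok))
    stop(sprintf("BED parse error at line %d: strand symbol '%s'",
                 which(!ok)[1], strand[which(!ok)[1]]), call. = FALSE)
  if (is.null(total_mapped)) total_mapped <- length(lines)
  mapped_read_set(
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               stringsAsFactors = FALSE),
    sample_id = sample_id, total_mapped = total_mapped)
}

#' Construct a gene annotation table
#'
#' One row per gene; the TSS is derived from the strand: `start` for `+`
#' genes, `end - 1` (the last covered base) for `-` genes.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return data.frame of class `GeneAnnotation` with an added `tss` column.
#' @export
gene_annotation <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (anyDuplicated(df$gene_id))
    stop(sprintf("duplicate gene_id '%s'",
                 df$gene_id[duplicated(df$gene_id)][1]), call. = FALSE)
  if (nrow(df) > 0 && any(df$start >= df$end))
    stop("gene with start >= end", call. = FALSE)
  s <- as.character(df$strand)
  s[s == "−"] <- "-"
  if (!all(s %in% c("+", "-")))
    stop("gene strand must be '+' or '-'", call. = FALSE)
  df$strand <- s
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df <- df[c("gene_id", "chrom", "start", "end", "strand", "tss")]
  rownames(df) <- NULL
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Read a gene annotation table
#'
#' Tab-delimited columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open), with or without a header line.
#'
#' @param path file path.
#' @return A [gene_annotation()] data.frame.
#' @export
read_gene_annotation <- function(path) {
  first <- read.table(path, sep = "\t", nrows = 1, header = FALSE,
                      colClasses = "character")
  has_header <- identical(tolower(first[[1]]), "gene_id")
  df <- read.table(path, sep = "\t", header = has_header,
                   col.names = c("gene_id", "chrom", "start", "end", "strand"),
                   colClasses = c("character", "character", "numeric",
                                  "numeric", "character"))
  gene_annotation(df)
}

#' Read a per-gene expression score matrix
#'
#' Expects a tab-delimited table with a header row of sample ids and gene ids
#' in the first column. Returns a genes-by-samples numeric matrix of
#' non-negative scores.
#'
#' @param path file path.
#' @return numeric matrix, rownames = gene ids, colnames = sample ids.
#' @export
read_expression_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    stop(sprintf("duplicate gene_id '%s' in expression table",
                 gene_ids[duplicated(gene_ids)][1]), call. = FALSE)
  m <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(gene_ids, colnames(m))))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid expression score for gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  num
}

#' Write an expression matrix
#'
#' Genes as rows (sorted by gene id), samples as columns; round-trips through
#' [read_expression_table()].
#'
#' @param mat genes-by-samples numeric matrix.
#' @param path output path.
#' @export
write_expression_table <- function(mat, path) {
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as deterministic TSV
#'
#' Rows are ordered by `gene_id` when present, else by (`chrom`, `start`) when
#' present, else left as-is; this makes re-runs byte-identical.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  if ("gene_id" %in% names(df)) {
    df <- df[order(df$gene_id), , drop = FALSE]
  } else if (all(c("chrom", "start") %in% names(df))) {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write called binding sites as BED6
#'
#' The name field encodes the site id and summit as `id:summit`, the score
#' column carries the summit RPM, strand is `.` (sites are unstranded).
#'
#' @param sites data.frame from [call_sites()].
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  bed <- data.frame(chrom = sites$chrom,
                    start = format(sites$start, scientific = FALSE, trim = TRUE),
                    end = format(sites$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("site_%d:%d", seq_len(nrow(sites)),
                                   as.integer(sites$summit)),
                    score = signif(sites$score, 6),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a TSS metaprofile as two-column offset/value text
#' @param profile data.frame from [tss_metaprofile()] (`offset`, `value`).
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  write.table(profile[c("offset", "value")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
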