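# small in-code fixtures shared across test files

# read set from bare 5' positions (36-bp plus-strand reads on one chromosome)
reads_at <- function(pos, chrom = "chr1", total_mapped = 1e6,
                     sample_id = "t") {
  mapped_read_set(
    data.frame(chrom = chrom, start = pos, end = pos + 36, strand = "+"),
    sample_id = sample_id, total_mapped = total_mapped)
}

empty_reads <- function(total_mapped = 1e6) {
  mapped_read_set(
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0)),
    total_mapped = total_mapped)
}

one_gene <- function(tss = 100000, strand = "+", chrom = "chr1",
                     len = 5000, gene_id = "g1") {
  if (strand == "+") {
    gene_annotation(data.frame(gene_id = gene_id, chrom = chrom,
                               start = tss, end = tss + len,
                               strand = strand))
  } else {
    gene_annotation(data.frame(gene_id = gene_id, chrom = chrom,
                               start = tss - len + 1, end = tss + 1,
                               strand = strand))
  }
}

# brute-force oracle: max windowed count over every integer centre
brute_force_rpm_max <- function(pos, tss, window, flank, total_mapped) {
  fl <- floor(window / 2)
  best <- 0
  for (center in (tss - flank):(tss + flank)) {
    cnt <- sum(pos >= center - fl & pos < center - fl + window)
    if (cnt > best) best <- cnt
  }
  1e6 * best / total_mapped
}

# small simulation scale for module-level tests
small_params <- function(...) {
  args <- utils::modifyList(list(n_chrom = 1, chrom_length = 8e6,
                                 n_genes = 200), list(...))
  do.call(sim_params, args)
}
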