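# Small in-code fixture builders shared across test files.

# alignment-record tibble in the shape produced by read_sam()
make_aln <- function(qname, flag, chrom = "chr1", pos = 1000L, mapq = 42L,
                     cigar = "150M", mate_chrom = chrom, mate_pos = pos,
                     tlen = 0L) {
  tibble::tibble(
    qname = qname, flag = as.integer(flag), chrom = chrom,
    pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
    mate_chrom = mate_chrom, mate_pos = as.integer(mate_pos),
    tlen = as.integer(tlen),
    unmapped = bitwAnd(as.integer(flag), 4L) > 0L
  )
}

# a proper pair covering fragment [start, end) on the given chain
make_pair <- function(qname, chrom, start, end, strand = "+",
                      read_len = 150L, mapq = 42L) {
  flags <- if (strand == "+") c(99L, 147L) else c(163L, 83L)
  dplyr::bind_rows(
    make_aln(qname, flags[1], chrom, start, mapq,
             cigar = paste0(read_len, "M"),
             mate_pos = end - read_len, tlen = end - start),
    make_aln(qname, flags[2], chrom, end - read_len, mapq,
             cigar = paste0(read_len, "M"),
             mate_pos = start, tlen = -(end - start))
  )
}

# fragment tibble with the attributes fragments_from_pairs() attaches
make_fragments <- function(x, library_id = "L1", total = nrow(x)) {
  attr(x, "library_id") <- library_id
  attr(x, "total_count") <- total
  x
}

# write lines to a temp file and return its path (for path-based readers)
textConnection_path <- function(lines) {
  path <- tempfile(fileext = ".sam")
  readr::write_lines(lines, path)
  path
}

# small deterministic simulation shared by integration-style tests:
# clean libraries (no background) at a scale where element regions pass the
# RPM threshold comfortably
small_sim_config <- function(seed = 11, n_fragments = 20000, ...) {
  regmapr::sim_config(
    seed = seed, n_chroms = 2, chrom_length = 3e6, n_genes = 40,
    n_elements = 30, n_fragments = n_fragments, background_fraction = 0,
    d2_fraction = 0.1, proximal_fraction = 0.3, ...
  )
}
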