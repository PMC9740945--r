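# Readers/writers for the plain-text formats the pipeline touches.
# BED is 0-based half-open and maps directly onto the internal convention;
# SAM POS and GFF3 are 1-based and converted at the boundary.

# drop readr's spec/problems attributes so readers return plain tibbles
plain_tbl <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV (`chrom`, `size`), as produced by
#'   `samtools faidx`-style chromosome size dumps (no header).
#' @return Tibble with columns `chrom` (character) and `size` (integer bp).
#'   Chromosome order of the file is preserved and used by all writers.
#' @export
read_genome <- function(path) {
  g <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       col_types = "cd", progress = FALSE)
  if (any(is.na(g$size)) || any(g$size <= 0)) abort("invalid chromosome size")
  plain_tbl(g)
}

#' @rdname read_genome
#' @param genome Genome tibble.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  readr::write_tsv(genome[, c("chrom", "size")], path, col_names = FALSE)
  invisible(path)
}

#' Read/write BED feature tracks
#'
#' Reads BED3/BED6 (tab-separated, 0-based half-open). Column 4 is read as
#' `name`, column 5 as `score`, column 6 as `strand`. `write_bed()` emits the
#' same columns (as many as are present) so that read -> write -> read is an
#' identity.
#'
#' @param path Path of a BED file.
#' @return Tibble with columns `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` present in the file.
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (ncol < 3) abort("BED requires at least 3 columns")
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6))]
  types <- substr("ciicdc", 1, min(ncol, 6))
  x <- suppressWarnings(
    readr::read_tsv(path, col_names = cols, col_types = types,
                    col_select = seq_len(min(ncol, 6)), progress = FALSE))
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    abort("non-integer BED coordinates")
  }
  x <- plain_tbl(x)
  check_intervals(x)
  x
}

#' @rdname read_bed
#' @param x Interval tibble.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- character(0)
  for (cl in cols) {           # BED columns are positional: stop at first gap
    if (cl %in% names(x)) keep <- c(keep, cl) else break
  }
  readr::write_tsv(x[, keep], path, col_names = FALSE)
  invisible(path)
}

#' Read paired-end alignment records from text SAM
#'
#' Parses the eleven mandatory SAM columns. Coordinates are converted to
#' 0-based (`pos = POS - 1`); records with `POS == 0` or the unmapped flag bit
#' (0x4) are retained but flagged via the `unmapped` column, per the SAM
#' specification. `"="` in RNEXT is resolved to the record's own chromosome.
#'
#' @param path Path to a SAM text file (header lines starting with `@` are
#'   skipped).
#' @return Tibble with columns `qname`, `flag`, `chrom`, `pos` (0-based
#'   leftmost), `mapq`, `cigar`, `mate_chrom`, `mate_pos` (0-based), `tlen`,
#'   `unmapped`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(qname = character(), flag = integer(), chrom = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  mate_chrom = character(), mate_pos = integer(),
                  tlen = integer(), unmapped = logical()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 12)
  if (any(f[, 11] == "")) abort("SAM record lacks mandatory columns")
  flag <- suppressWarnings(as.integer(f[, 2]))
  pos1 <- suppressWarnings(as.integer(f[, 4]))
  pnext1 <- suppressWarnings(as.integer(f[, 8]))
  if (any(is.na(flag)) || any(is.na(pos1))) abort("malformed SAM numeric field")
  mate_chrom <- ifelse(f[, 7] == "=", f[, 3], f[, 7])
  tibble(
    qname = f[, 1],
    flag = flag,
    chrom = f[, 3],
    pos = ifelse(pos1 == 0L, NA_integer_, pos1 - 1L),
    mapq = as.integer(f[, 5]),
    cigar = f[, 6],
    mate_chrom = mate_chrom,
    mate_pos = ifelse(pnext1 == 0L, NA_integer_, pnext1 - 1L),
    tlen = as.integer(f[, 9]),
    unmapped = bitwAnd(flag, 4L) > 0L | pos1 == 0L
  )
}

# reference-consumed length of a CIGAR string (M/D/N/=/X ops); "*" -> NA
cigar_ref_length <- function(cigar) {
  u <- unique(cigar)
  len <- vapply(u, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- stringr::str_match_all(cg, "(\\d+)([MIDNSHP=X])")[[1]]
    sum(as.integer(ops[ops[, 3] %in% c("M", "D", "N", "=", "X"), 2]))
  }, integer(1))
  unname(len[match(cigar, u)])
}

#' Read a gene annotation (GFF3 or BED12)
#'
#' One record per gene; strand is mandatory because the transcription start
#' site (TSS) is the strand-aware 5' end. For GFF3, records of type `gene`
#' are used when present (otherwise all records), and the gene id is taken
#' from the `ID` attribute (falling back to `gene_id`/`Name`).
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` (BED12/BED6) file.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span) and `tss`, `tes` (0-based positions of the 5'
#'   and 3' ends).
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    meta <- S4Vectors::mcols(gr)
    if ("type" %in% names(meta) && any(meta$type == "gene")) {
      gr <- gr[meta$type == "gene"]
      meta <- S4Vectors::mcols(gr)
    }
    id <- NULL
    for (cand in c("ID", "gene_id", "Name")) {
      if (cand %in% names(meta) && !all(is.na(meta[[cand]]))) {
        id <- as.character(meta[[cand]])
        break
      }
    }
    if (is.null(id)) abort("GFF3 records lack an ID/gene_id attribute")
    genes <- tibble(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
  } else {
    x <- read_bed(path)
    if (!all(c("name", "strand") %in% names(x))) {
      abort("BED gene annotation requires name and strand columns")
    }
    genes <- tibble(gene_id = x$name, chrom = x$chrom, strand = x$strand,
                    start = x$start, end = x$end)
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene annotation with missing strand")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                       collapse = ", ")))
  }
  mutate(genes,
         tss = if_else(.data$strand == "+", .data$start, .data$end - 1L),
         tes = if_else(.data$strand == "+", .data$end - 1L, .data$start))
}

#' Write a gene annotation as GFF3
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `start`, `end`).
#' @param path Output path.
#' @export
write_gene_annotation <- function(genes, path) {
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tregmapr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$chrom, genes$start + 1L, genes$end, genes$strand,
            genes$gene_id)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write intervals as GFF3 features
#'
#' Mirrors the intermediate GFF representation of called regions: one
#' feature per interval, score column from `rpm` (or `score`) when present.
#'
#' @param x Interval tibble (optionally with `rpm`/`score`, `strand`,
#'   `region_id`/`name`).
#' @param path Output path.
#' @param type Feature type written in column 3 (default `"region"`).
#' @param source Source label for column 2.
#' @export
write_gff3 <- function(x, path, type = "region", source = "regmapr") {
  pick <- function(cols, default) {
    for (cl in cols) if (cl %in% names(x)) return(x[[cl]])
    default
  }
  score <- pick(c("rpm", "score"), rep(".", nrow(x)))
  id <- pick(c("region_id", "name"),
             sprintf("%s_%05d", type, seq_len(nrow(x))))
  strand <- pick("strand", rep(".", nrow(x)))
  strand[strand == "*"] <- "."
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\tID=%s",
                     x$chrom, source, type, x$start + 1L, x$end,
                     as.character(score), strand, id))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write fragment mate pairs as BEDPE
#'
#' Emits the 10-column BEDPE produced by BAM-to-BED conversion of proper
#' pairs (chrom1, start1, end1, chrom2, start2, end2, name, score, strand1,
#' strand2). Requires mate interval columns as produced by
#' [fragments_from_pairs()].
#'
#' @param fragments Fragment tibble with `start1`, `end1`, `start2`, `end2`.
#' @param path Output path.
#' @export
write_bedpe <- function(fragments, path) {
  need <- c("chrom", "start1", "end1", "start2", "end2", "qname", "strand")
  if (!all(need %in% names(fragments))) {
    abort("fragment table lacks mate coordinates; run fragments_from_pairs()")
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t.\t%s\t%s",
                   fragments$chrom, fragments$start1, fragments$end1,
                   fragments$chrom, fragments$start2, fragments$end2,
                   fragments$qname, fragments$strand, fragments$strand)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read an expression table (gene id -> FPKM)
#'
#' @param path Two-column TSV with a header (`gene_id`, `fpkm`).
#' @return Tibble `gene_id`, `fpkm`; FPKM must be finite and non-negative.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  names(x)[1:2] <- c("gene_id", "fpkm")
  if (any(!is.finite(x$fpkm)) || any(x$fpkm < 0)) {
    abort("FPKM values must be finite and >= 0")
  }
  plain_tbl(x)
}

#' Read a gene-category annotation
#'
#' @param path Two-column TSV with a header (`gene_id`, `category`); a gene
#'   may appear under several categories.
#' @return Long tibble `gene_id`, `category`.
#' @export
read_categories <- function(path) {
  x <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(x)[1:2] <- c("gene_id", "category")
  if (any(x$gene_id == "")) abort("empty gene id in category table")
  plain_tbl(x)
}
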