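# Interval algebra on tibbles of 0-based half-open intervals
# (chrom, start, end[, strand]). GenomicRanges does the heavy lifting; all
# conversions to its 1-based closed convention are confined to this file.

#' Validate an interval tibble
#'
#' Checks the basic contract of an interval table: required columns, integer
#' coordinates, `0 <= start < end`, and (optionally) containment within the
#' chromosomes of a genome table.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (`"+"`, `"-"` or `"*"`). Coordinates are 0-based half-open.
#' @param genome Optional genome table (see [read_genome()]) with columns
#'   `chrom` and `size`; when supplied, every interval must lie within
#'   `[0, size)` of a known chromosome.
#' @return `x` invisibly, as a tibble; errors describe the first violation.
#' @export
check_intervals <- function(x, genome = NULL) {
  x <- as_tibble(x)
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
      abort("interval coordinates must be finite")
    }
    if (any(x$start < 0)) abort("interval start < 0")
    if (any(x$end <= x$start)) abort("interval end <= start (zero/negative length)")
    if ("strand" %in% names(x) &&
        !all(x$strand %in% c("+", "-", "*"))) {
      abort("strand must be one of '+', '-', '*'")
    }
    if (!is.null(genome)) {
      sizes <- setNames(genome$size, genome$chrom)
      unknown <- setdiff(unique(x$chrom), names(sizes))
      if (length(unknown) > 0) {
        abort(paste0("chromosome(s) absent from genome: ",
                     paste(unknown, collapse = ", ")))
      }
      if (any(x$end > sizes[x$chrom])) {
        abort("interval extends beyond chromosome end")
      }
    }
  }
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_gr <- function(x, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# GRanges -> tibble (0-based half-open)
gr_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Parse UCSC-style region strings
#'
#' Converts display coordinates of the form `"chr13:99,498,575-99,499,229"`
#' (1-based, fully closed, optional thousands separators and internal
#' whitespace) into 0-based half-open intervals, so that the interval length
#' equals `printed_end - printed_start + 1`.
#'
#' @param text Character vector of region strings.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' parse_region_string("chr1:1-1")          # [0, 1), length 1
#' parse_region_string("chr13:99,498,575- 99,499,229")
#' @export
parse_region_string <- function(text) {
  m <- stringr::str_match(
    stringr::str_squish(text),
    "^([^:\\s]+)\\s*:\\s*([0-9][0-9,]*)\\s*-\\s*([0-9][0-9,]*)$"
  )
  if (any(is.na(m[, 1]))) {
    abort(paste0("malformed region string: ",
                 paste(text[is.na(m[, 1])], collapse = ", ")))
  }
  start1 <- as.numeric(gsub(",", "", m[, 3], fixed = TRUE))
  end1 <- as.numeric(gsub(",", "", m[, 4], fixed = TRUE))
  if (any(start1 < 1)) abort("printed coordinates are 1-based; start < 1")
  if (any(start1 > end1)) abort("region start exceeds end after normalization")
  tibble(chrom = m[, 2], start = as.integer(start1 - 1), end = as.integer(end1))
}

#' Interval length
#'
#' @param x Interval tibble.
#' @return Integer vector of lengths (`end - start`) in bp.
#' @export
interval_length <- function(x) x$end - x$start

#' Merge overlapping or nearby intervals
#'
#' Collapses intervals that overlap by at least 1 bp or whose gap is at most
#' `max_gap` bp (so book-ended intervals merge at the default `max_gap = 0`).
#'
#' @param x Interval tibble.
#' @param max_gap Maximum gap (bp) across which to merge; default 0 merges
#'   book-ended but not separated intervals.
#' @param stranded If `TRUE`, merge within strands only.
#' @return Tibble of merged intervals, sorted by (`chrom`, `start`), with a
#'   `strand` column (set to `"*"` when `stranded = FALSE`).
#' @export
merge_intervals <- function(x, max_gap = 0L, stranded = FALSE) {
  check_intervals(x)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  gr <- as_gr(x, use_strand = stranded)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               ignore.strand = !stranded)
  out <- gr_tbl(red)
  if (!stranded) out$strand <- "*"
  arrange(out, .data$chrom, .data$start, .data$end, .data$strand)
}

#' Flag intervals overlapping a feature track
#'
#' An interval is flagged if it shares at least 1 bp with any interval of the
#' track (strict half-open semantics: book-ended intervals do not overlap).
#' Strand is ignored, matching the any-overlap intersection used for feature
#' tracks.
#'
#' @param x Interval tibble (query).
#' @param track Interval tibble (subject), e.g. a BED track from [read_bed()].
#' @return `x` with two extra columns: `overlaps` (logical) and `n_hits`
#'   (number of track intervals hit).
#' @export
intersect_any <- function(x, track) {
  x <- check_intervals(x)
  if (nrow(x) == 0) {
    return(mutate(x, overlaps = logical(0), n_hits = integer(0)))
  }
  if (nrow(track) == 0) {
    return(mutate(x, overlaps = FALSE, n_hits = 0L))
  }
  hits <- GenomicRanges::countOverlaps(
    as_gr(x, use_strand = FALSE), as_gr(track, use_strand = FALSE),
    minoverlap = 1L, ignore.strand = TRUE
  )
  mutate(x, overlaps = hits > 0, n_hits = as.integer(hits))
}

#' Fraction of intervals overlapping a track
#'
#' @inheritParams intersect_any
#' @return A single number: the fraction of `x` intervals sharing >= 1 bp with
#'   the track. Errors on an empty `x` (the fraction is undefined).
#' @export
overlap_fraction <- function(x, track) {
  if (nrow(x) == 0) abort("overlap fraction undefined for an empty region set")
  mean(intersect_any(x, track)$overlaps)
}

#' Rename chromosomes
#'
#' Chromosome matching is exact everywhere in the package (no silent "chr"
#' aliasing); this utility performs explicit renames instead.
#'
#' @param x Interval tibble.
#' @param mapping Named character vector, `old_name = "new_name"`.
#' @return `x` with chromosomes renamed.
#' @export
rename_chroms <- function(x, mapping) {
  hit <- x$chrom %in% names(mapping)
  x$chrom[hit] <- unname(mapping[x$chrom[hit]])
  x
}
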