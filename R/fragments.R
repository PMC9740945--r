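# Fragment recovery: from filtered paired-end alignment records back to the
# cloned library fragments and their orientation.

# flag bits used by the filter
FLAG_PROPER    <- 0x2L
FLAG_UNMAPPED  <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPL     <- 0x800L

# flag combinations identifying the DNA chain of a proper pair
PLUS_FLAGS  <- c(99L, 147L)
MINUS_FLAGS <- c(83L, 163L)

#' Filter alignment records
#'
#' Keeps properly-paired primary alignments: flag bit 0x2 set, bits 0x4
#' (unmapped), 0x100 (secondary) and 0x800 (supplementary) unset, and
#' `MAPQ >= mapq_min`. Input order is preserved and the operation is
#' idempotent.
#'
#' @param records Alignment tibble from [read_sam()].
#' @param mapq_min Minimum mapping quality (default 10).
#' @return The retained records.
#' @export
filter_alignments <- function(records, mapq_min = 10L) {
  keep <- bitwAnd(records$flag, FLAG_PROPER) > 0L &
    bitwAnd(records$flag, FLAG_UNMAPPED) == 0L &
    bitwAnd(records$flag, FLAG_SECONDARY) == 0L &
    bitwAnd(records$flag, FLAG_SUPPL) == 0L &
    !is.na(records$mapq) & records$mapq >= mapq_min
  records[keep, , drop = FALSE]
}

#' Assign the DNA chain from the alignment flag
#'
#' Proper pairs report the originating chain through the flag combinations
#' 99/147 (plus) and 83/163 (minus); any other flag value identifies no chain
#' and the record is marked excluded (`NA` strand).
#'
#' @param records Alignment tibble (normally after [filter_alignments()]).
#' @return `records` with a `strand` column: `"+"`, `"-"`, or `NA` (excluded).
#' @export
assign_strand <- function(records) {
  mutate(records, strand = case_when(
    .data$flag %in% PLUS_FLAGS ~ "+",
    .data$flag %in% MINUS_FLAGS ~ "-",
    TRUE ~ NA_character_
  ))
}

#' Reconstruct cloned fragments from mate pairs
#'
#' Each read-pair id contributes one fragment spanning the outer coordinates
#' of its two mates (leftmost aligned base to rightmost aligned base, equal to
#' `|TLEN|` for well-formed pairs). The mate end is derived from the
#' reference-consumed CIGAR length; soft-clips are ignored. Pairs are dropped
#' (and counted) when a mate is missing (orphan), when mates map to different
#' chromosomes, or when the two mates imply conflicting chain assignments.
#'
#' @param records Alignment tibble after [filter_alignments()] and
#'   [assign_strand()]. Records with `NA` strand are excluded up front.
#' @param library_id Library label stored alongside the fragments.
#' @return A tibble of fragments (`chrom`, `start`, `end`, `strand`, `qname`,
#'   mate intervals `start1/end1/start2/end2`, `library`) with attributes
#'   `library_id`, `total_count` (number of fragments), and a `counts` list
#'   (`n_qnames`, `n_excluded_strand`, `n_orphans`, `n_discordant`).
#' @export
fragments_from_pairs <- function(records, library_id = "L1") {
  if (!"strand" %in% names(records)) records <- assign_strand(records)
  n_qnames <- dplyr::n_distinct(records$qname)
  excl <- is.na(records$strand)
  n_excluded <- dplyr::n_distinct(records$qname[excl])
  rec <- records[!excl, , drop = FALSE]

  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), qname = character(),
                  start1 = integer(), end1 = integer(),
                  start2 = integer(), end2 = integer(), library = character())
  finish <- function(frag, orphans, discordant) {
    attr(frag, "library_id") <- library_id
    attr(frag, "total_count") <- nrow(frag)
    attr(frag, "counts") <- list(
      n_qnames = n_qnames, n_excluded_strand = n_excluded,
      n_orphans = orphans, n_discordant = discordant
    )
    frag
  }
  if (nrow(rec) == 0) return(finish(empty, 0L, 0L))

  rec$reflen <- cigar_ref_length(rec$cigar)
  rec$reflen[is.na(rec$reflen)] <- abs(rec$tlen[is.na(rec$reflen)])
  ord <- order(rec$qname, rec$pos)
  rec <- rec[ord, , drop = FALSE]
  runs <- rle(rec$qname)
  orphan_q <- runs$values[runs$lengths == 1L]
  bad_multi <- runs$values[runs$lengths > 2L]
  n_orphans <- length(orphan_q)
  pair_q <- runs$values[runs$lengths == 2L]
  rec <- rec[rec$qname %in% pair_q, , drop = FALSE]
  if (nrow(rec) == 0) return(finish(empty, n_orphans, length(bad_multi)))

  i1 <- seq(1L, nrow(rec), by = 2L)  # leftmost mate after ordering
  i2 <- i1 + 1L
  same_chrom <- rec$chrom[i1] == rec$chrom[i2]
  same_strand <- rec$strand[i1] == rec$strand[i2]
  ok <- same_chrom & same_strand & !is.na(rec$pos[i1]) & !is.na(rec$pos[i2])
  n_discordant <- sum(!ok) + length(bad_multi)

  frag <- tibble(
    chrom = rec$chrom[i1][ok],
    start = rec$pos[i1][ok],
    end = pmax(rec$pos[i1][ok] + rec$reflen[i1][ok],
               rec$pos[i2][ok] + rec$reflen[i2][ok]),
    strand = rec$strand[i1][ok],
    qname = rec$qname[i1][ok],
    start1 = rec$pos[i1][ok],
    end1 = rec$pos[i1][ok] + rec$reflen[i1][ok],
    start2 = rec$pos[i2][ok],
    end2 = rec$pos[i2][ok] + rec$reflen[i2][ok],
    library = library_id
  )
  frag <- arrange(frag, .data$chrom, .data$start, .data$end)
  finish(frag, n_orphans, n_discordant)
}

#' Summary counts of a fragment set
#'
#' @param fragments Result of [fragments_from_pairs()].
#' @return One-row tibble: `library`, `n_fragments`, `n_qnames`,
#'   `n_excluded_strand`, `n_orphans`, `n_discordant`.
#' @export
fragment_stats <- function(fragments) {
  cts <- attr(fragments, "counts") %||%
    list(n_qnames = NA_integer_, n_excluded_strand = NA_integer_,
         n_orphans = NA_integer_, n_discordant = NA_integer_)
  tibble(
    library = attr(fragments, "library_id") %||% NA_character_,
    n_fragments = nrow(fragments),
    n_qnames = cts$n_qnames,
    n_excluded_strand = cts$n_excluded_strand,
    n_orphans = cts$n_orphans,
    n_discordant = cts$n_discordant
  )
}
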