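# Region calling: merge fragments per orientation, quantify RPM, apply the
# strict RPM threshold, and union libraries into the unique region map.

#' Merge fragments of the same orientation
#'
#' Within each strand, fragments overlapping by >= 1 bp or separated by at
#' most `max_gap` bp (book-ended fragments merge at the default 0) collapse
#' into a single region spanning their union.
#'
#' @param fragments Fragment tibble (strand-assigned).
#' @param max_gap Maximum gap (bp) across which fragments merge; default 0.
#' @return Tibble of strand-specific regions (`chrom`, `start`, `end`,
#'   `strand`), non-overlapping within each strand and sorted.
#' @export
merge_same_strand <- function(fragments, max_gap = 0L) {
  merge_intervals(fragments, max_gap = max_gap, stranded = TRUE)
}

#' Quantify fragments per region and RPM
#'
#' Counts the library's fragments overlapping each region by >= 1 bp on the
#' same strand (unstranded regions count fragments of both strands) and
#' normalizes to reads per million: `rpm = count * 1e6 / total_count`.
#'
#' @param regions Region tibble (normally from [merge_same_strand()]).
#' @param fragments Fragment tibble of the same library.
#' @param total_count Normalization denominator; defaults to the fragment
#'   set's retained-fragment total.
#' @return `regions` with `n_fragments` and `rpm` columns.
#' @export
quantify_rpm <- function(regions, fragments, total_count = NULL) {
  total_count <- total_count %||% attr(fragments, "total_count") %||% nrow(fragments)
  if (total_count == 0) abort("cannot normalize RPM with zero total fragments")
  if (nrow(regions) == 0) {
    return(mutate(regions, n_fragments = integer(0), rpm = numeric(0)))
  }
  cnt <- GenomicRanges::countOverlaps(
    as_gr(regions), as_gr(fragments), minoverlap = 1L
  )
  mutate(regions, n_fragments = as.integer(cnt),
         rpm = cnt * 1e6 / total_count)
}

#' Apply the RPM threshold
#'
#' Retains regions with RPM strictly greater than `rpm_min` (a region at
#' exactly the threshold is dropped).
#'
#' @param regions Region tibble with an `rpm` column.
#' @param rpm_min RPM threshold (default 10).
#' @return The retained regions.
#' @export
threshold_rpm <- function(regions, rpm_min = 10) {
  filter(regions, .data$rpm > rpm_min)
}

#' Call candidate regulatory regions for one library
#'
#' The per-library caller: merge fragments within each orientation, count
#' fragments and compute RPM per strand-specific region, combine the two
#' orientations, then apply the strict RPM threshold.
#'
#' @param fragments Fragment tibble from [fragments_from_pairs()].
#' @param rpm_min RPM threshold (default 10, strict).
#' @param max_gap Merge gap in bp (default 0).
#' @param count_mates If `TRUE`, count individual mates (2 per fragment) with
#'   a read-based denominator instead of fragments.
#' @return Tibble of called regions (`chrom`, `start`, `end`, `strand`,
#'   `n_fragments`, `rpm`, `library`), sorted by position.
#' @export
call_regions <- function(fragments, rpm_min = 10, max_gap = 0L,
                         count_mates = FALSE) {
  regions <- merge_same_strand(fragments, max_gap = max_gap)
  total <- attr(fragments, "total_count") %||% nrow(fragments)
  regions <- quantify_rpm(regions, fragments, total_count = total)
  if (count_mates) {
    # every aligned mate of a counted fragment overlaps its region, so mate
    # counting doubles both numerator and denominator
    regions <- mutate(regions, n_fragments = 2L * .data$n_fragments,
                      rpm = .data$n_fragments * 1e6 / (2 * total))
  }
  regions <- threshold_rpm(regions, rpm_min = rpm_min)
  regions <- arrange(regions, .data$chrom, .data$start, .data$end)
  mutate(regions, library = attr(fragments, "library_id") %||% "L1")
}

#' Union per-library region maps into the unique region map
#'
#' Merges the already-thresholded region sets of all libraries, by default
#' blind to strand (the unique regions of the final map are unstranded), and
#' records which libraries contributed to each merged region.
#'
#' @param maps A list of per-library region tibbles (each with a `library`
#'   column), or a single combined tibble.
#' @param stranded If `TRUE`, keep strand-specific regions separate.
#' @return Tibble with `region_id`, `chrom`, `start`, `end`, `strand`,
#'   `libraries` (comma-separated contributors) and `n_libraries`.
#' @export
union_libraries <- function(maps, stranded = FALSE) {
  combined <- if (is.data.frame(maps)) as_tibble(maps) else bind_rows(maps)
  if (!"library" %in% names(combined)) combined$library <- "L1"
  merged <- merge_intervals(combined, max_gap = 0L, stranded = stranded)
  if (nrow(merged) == 0) {
    return(mutate(merged, region_id = character(), libraries = character(),
                  n_libraries = integer()))
  }
  hits <- GenomicRanges::findOverlaps(
    as_gr(merged, use_strand = stranded), as_gr(combined, use_strand = stranded),
    minoverlap = 1L, ignore.strand = !stranded
  )
  libs <- tibble(
    i = S4Vectors::queryHits(hits),
    library = combined$library[S4Vectors::subjectHits(hits)]
  ) %>%
    distinct() %>%
    arrange(.data$i, .data$library) %>%
    group_by(.data$i) %>%
    summarise(libraries = paste(.data$library, collapse = ","),
              n_libraries = dplyr::n(), .groups = "drop")
  merged %>%
    mutate(i = row_number()) %>%
    left_join(libs, by = "i") %>%
    mutate(region_id = sprintf("region_%05d", .data$i)) %>%
    select("region_id", "chrom", "start", "end", "strand",
           "libraries", "n_libraries")
}

#' Run the full caller over several SAM files
#'
#' Convenience wrapper: parse each library's SAM, filter and strand-assign the
#' records, reconstruct fragments, call per-library regions, and union the
#' libraries into the unique region map.
#'
#' @param sam_paths Character vector of SAM file paths, one per library.
#' @param library_ids Library labels (default `L1`, `L2`, ...).
#' @param mapq_min Minimum MAPQ (default 10).
#' @param rpm_min RPM threshold (default 10, strict).
#' @param max_gap Merge gap in bp (default 0).
#' @param stranded_union Keep strands separate in the final union.
#' @return List with `map` (the unique region map), `library_regions`
#'   (per-library called regions) and `fragments` (per-library fragment sets).
#' @export
region_map_from_sam <- function(sam_paths,
                                library_ids = paste0("L", seq_along(sam_paths)),
                                mapq_min = 10L, rpm_min = 10, max_gap = 0L,
                                stranded_union = FALSE) {
  frags <- purrr::map2(sam_paths, library_ids, function(p, id) {
    read_sam(p) %>%
      filter_alignments(mapq_min = mapq_min) %>%
      assign_strand() %>%
      fragments_from_pairs(library_id = id)
  })
  names(frags) <- library_ids
  regions <- purrr::map(frags, call_regions, rpm_min = rpm_min,
                        max_gap = max_gap)
  list(map = union_libraries(regions, stranded = stranded_union),
       library_regions = regions,
       fragments = frags)
}
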