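# Feature-track enrichment of the region map versus size- and
# chromosome-matched random regions.

#' Generate a matched random region set
#'
#' For every template region, places an interval of identical length
#' uniformly at random on the same chromosome, resampling placements that
#' cross a chromosome end or a declared assembly gap. Count, length multiset
#' and per-chromosome distribution therefore match the template exactly.
#'
#' @param template Region tibble to match.
#' @param genome Genome tibble (`chrom`, `size`).
#' @param seed Integer seed; the same seed reproduces the same placements.
#' @param gaps Optional interval tibble of assembly gaps to avoid.
#' @param max_tries Resampling attempts per region before giving up.
#' @return Tibble of random regions (`chrom`, `start`, `end`) in template
#'   order.
#' @export
shuffle_matched <- function(template, genome, seed, gaps = NULL,
                            max_tries = 1000L) {
  check_intervals(template, genome)
  sizes <- setNames(genome$size, genome$chrom)
  len <- template$end - template$start
  if (any(len > sizes[template$chrom])) {
    bad <- which(len > sizes[template$chrom])[1]
    abort(sprintf("region %s:%d-%d is longer than its chromosome",
                  template$chrom[bad], template$start[bad], template$end[bad]))
  }
  n <- nrow(template)
  starts <- integer(n)
  gap_gr <- if (!is.null(gaps) && nrow(gaps) > 0) as_gr(gaps, use_strand = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  max_start <- sizes[template$chrom] - len   # starts uniform on [0, size - len]
  starts <- floor(runif(n) * (max_start + 1))
  if (!is.null(gap_gr)) {
    for (tries in seq_len(max_tries)) {
      cand <- GenomicRanges::GRanges(
        template$chrom, IRanges::IRanges(starts + 1, width = len))
      bad <- GenomicRanges::countOverlaps(cand, gap_gr) > 0
      if (!any(bad)) break
      if (tries == max_tries) {
        abad <- which(bad)[1]
        abort(sprintf(
          "could not place region of length %d on %s outside gaps",
          len[abad], template$chrom[abad]))
      }
      starts[bad] <- floor(runif(sum(bad)) * (max_start[bad] + 1))
    }
  }
  tibble(chrom = template$chrom, start = as.integer(starts),
         end = as.integer(starts + len))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Permutation enrichment of a region map in a feature track
#'
#' Compares the observed fraction of regions overlapping the track with the
#' fractions obtained for `n_replicates` matched random region sets. The
#' enrichment ratio is `observed / mean(null)`; the upper-tail empirical
#' p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_replicates)`, so it is never zero.
#'
#' @param map Region map tibble.
#' @param track Feature-track tibble.
#' @param genome Genome tibble.
#' @param n_replicates Number of matched random sets (default 100).
#' @param seed Base seed (default 17); replicate r uses `seed + r`.
#' @param gaps Optional gap intervals passed to [shuffle_matched()].
#' @param track_name Label stored in the result.
#' @return A `regmap_enrichment` object; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
enrichment_test <- function(map, track, genome, n_replicates = 100L,
                            seed = 17L, gaps = NULL,
                            track_name = "track") {
  stopifnot(n_replicates >= 1)
  observed <- overlap_fraction(map, track)
  null_fractions <- vapply(seq_len(n_replicates), function(r) {
    overlap_fraction(shuffle_matched(map, genome, seed = seed + r,
                                     gaps = gaps), track)
  }, numeric(1))
  structure(
    list(
      track_name = track_name,
      n_regions = nrow(map),
      observed_fraction = observed,
      null_fractions = null_fractions,
      null_mean = mean(null_fractions),
      ratio = observed / mean(null_fractions),
      empirical_p = (1 + sum(null_fractions >= observed)) /
        (1 + n_replicates),
      n_replicates = n_replicates,
      seed = seed
    ),
    class = "regmap_enrichment"
  )
}

#' @export
print.regmap_enrichment <- function(x, ...) {
  cat(sprintf(
    "Enrichment of %d regions in '%s'\n  observed: %.1f%%  null mean: %.1f%% (%d matched random sets)\n  ratio: %.2f  empirical p: %.4g\n",
    x$n_regions, x$track_name, 100 * x$observed_fraction,
    100 * x$null_mean, x$n_replicates, x$ratio, x$empirical_p))
  invisible(x)
}

#' Split track peak scores by region-map overlap
#'
#' Splits a scored feature track (e.g. MACS-scored H3K27ac peaks) into peaks
#' that are overlapped by the region map and peaks that are not, and compares
#' the two score samples with the two-sided rank-sum test.
#'
#' @param map Region map tibble.
#' @param track Scored track tibble (requires a `score` column).
#' @return A `regmap_colocalization` object with `$scores` (tibble `score`,
#'   `overlapped`), `$test` (a `regmap_ranksum`), and box-plot descriptors in
#'   `$summary`. Errors when every peak (or no peak) is overlapped, because
#'   the split is degenerate.
#' @export
score_colocalization <- function(map, track) {
  if (!"score" %in% names(track)) abort("track has no per-interval scores")
  flagged <- intersect_any(track, map)
  if (all(flagged$overlaps) || !any(flagged$overlaps)) {
    abort("degenerate split: every peak on one side of the overlap partition")
  }
  scores <- tibble(score = flagged$score, overlapped = flagged$overlaps)
  test <- rank_sum_test(scores$score[scores$overlapped],
                        scores$score[!scores$overlapped],
                        fpkm_min = -Inf)
  structure(
    list(scores = scores, test = test,
         summary = bind_rows(
           mutate(box_stats(scores$score[scores$overlapped]),
                  group = "overlapped", .before = 1),
           mutate(box_stats(scores$score[!scores$overlapped]),
                  group = "not_overlapped", .before = 1))),
    class = "regmap_colocalization"
  )
}

#' @export
print.regmap_colocalization <- function(x, ...) {
  n <- table(x$scores$overlapped)
  cat(sprintf(
    "Peak scores by map overlap: %d overlapped vs %d not\n  medians: %.1f vs %.1f;  rank-sum p = %.3g (%s)\n",
    sum(x$scores$overlapped), sum(!x$scores$overlapped),
    median(x$scores$score[x$scores$overlapped]),
    median(x$scores$score[!x$scores$overlapped]),
    x$test$p_two_sided, x$test$method))
  invisible(x)
}
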