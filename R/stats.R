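# Group statistics: rank-sum expression comparisons with the FPKM cutoff,
# category composition percentages, hypergeometric fold enrichment with BH
# correction, and the TSS-distance profile.

#' Two-sided Mann-Whitney rank-sum test with expression cutoff
#'
#' Values below `fpkm_min` are removed from both groups before ranking
#' (mirroring the 0.5 FPKM cutoff used for expression comparisons). The test
#' is exact (full enumeration) when both groups have at most `exact_max`
#' values and there are no ties; otherwise the normal approximation with
#' midrank tie correction and continuity correction is used.
#'
#' @param a,b Numeric samples (e.g. FPKM values of two gene groups).
#' @param fpkm_min Cutoff applied to both groups before testing (default
#'   0.5; use `-Inf` to disable).
#' @param exact_max Largest per-group size for the exact test (default 8).
#' @return A `regmap_ranksum` object: `u_statistic` (U of the first group),
#'   `n1`, `n2`, `p_two_sided`, `method` (`"exact"`/`"normal_approx"`), and
#'   box-plot descriptors for both groups in `$summary`.
#' @export
rank_sum_test <- function(a, b, fpkm_min = 0.5, exact_max = 8L) {
  a <- a[a >= fpkm_min]
  b <- b[b >= fpkm_min]
  if (length(a) == 0 || length(b) == 0) {
    abort("degenerate groups: one side is empty after the expression cutoff")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  structure(
    list(
      u_statistic = unname(wt$statistic),
      n1 = length(a), n2 = length(b),
      p_two_sided = wt$p.value,
      method = if (exact) "exact" else "normal_approx",
      summary = bind_rows(
        mutate(box_stats(a), group = "a", .before = 1),
        mutate(box_stats(b), group = "b", .before = 1)
      )
    ),
    class = "regmap_ranksum"
  )
}

#' @export
print.regmap_ranksum <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney rank-sum (%s): U = %g, n = %d/%d, two-sided p = %.4g\n",
    x$method, x$u_statistic, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Box-plot descriptors of a sample
#'
#' Median, quartiles, 1.5*IQR whiskers and min-max range, as drawn on
#' box-and-whisker expression plots. Descriptive only; no values are trimmed
#' before testing.
#'
#' @param x Numeric vector.
#' @return One-row tibble: `n`, `min`, `whisker_lo`, `q1`, `median`, `q3`,
#'   `whisker_hi`, `max`.
#' @export
box_stats <- function(x) {
  q1 <- unname(quantile(x, 0.25))
  q3 <- unname(quantile(x, 0.75))
  iqr <- q3 - q1
  tibble(
    n = length(x), min = min(x),
    whisker_lo = min(x[x >= q1 - 1.5 * iqr]),
    q1 = q1, median = median(x), q3 = q3,
    whisker_hi = max(x[x <= q3 + 1.5 * iqr]),
    max = max(x)
  )
}

#' Category composition of gene groups
#'
#' For every (group, category) pair, the percentage of the group's genes
#' annotated with the category. Categories may overlap, so percentages within
#' a group can sum to more than 100.
#'
#' @param groups Gene-group tibble from [partition_genes()] (logical columns
#'   `P`, `D1`, `D2`), or any tibble with `gene_id` plus logical membership
#'   columns named in `group_cols`.
#' @param categories Long tibble `gene_id`, `category`.
#' @param group_cols Names of the logical membership columns to report.
#' @return Tibble `group`, `category`, `n_group`, `n_in_category`, `percent`.
#' @export
group_composition <- function(groups, categories,
                              group_cols = c("P", "D1", "D2")) {
  group_cols <- intersect(group_cols, names(groups))
  cats <- unique(categories$category)
  out <- purrr::map(group_cols, function(g) {
    members <- groups$gene_id[groups[[g]]]
    if (length(members) == 0) {
      abort(sprintf("group '%s' is empty; composition undefined", g))
    }
    purrr::map(cats, function(cl) {
      hits <- sum(members %in% categories$gene_id[categories$category == cl])
      tibble(group = g, category = cl, n_group = length(members),
             n_in_category = hits, percent = 100 * hits / length(members))
    }) %>% bind_rows()
  }) %>% bind_rows()
  out
}

#' Hypergeometric fold enrichment of categories in a gene set
#'
#' For each category, computes `fold = (k/n) / (K/N)` where `k` is the number
#' of set genes in the category, `n` the gene-set size, `K` the category size
#' within the universe, and `N` the universe size, with an upper-tail
#' hypergeometric p-value `P(X >= k)` and Benjamini-Hochberg adjustment
#' across the categories tested in the call. `ease = TRUE` applies the
#' conservative EASE variant (one hit removed: `P(X >= k)` computed at
#' `k - 1`).
#'
#' @param gene_set Character vector of gene ids (will be intersected with the
#'   universe).
#' @param categories Long tibble `gene_id`, `category`.
#' @param universe Character vector of all gene ids under consideration.
#' @param ease Use the EASE-modified score (default `FALSE`).
#' @return Tibble `category`, `k`, `n`, `K`, `N`, `fold`, `p`, `p_adj`,
#'   sorted by `p`.
#' @export
fold_enrichment <- function(gene_set, categories, universe, ease = FALSE) {
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  N <- length(universe)
  n <- length(gene_set)
  if (n == 0 || N == 0) abort("degenerate enrichment: empty gene set or universe")
  out <- categories %>%
    filter(.data$gene_id %in% universe) %>%
    distinct(.data$gene_id, .data$category) %>%
    group_by(.data$category) %>%
    summarise(K = dplyr::n(),
              k = sum(.data$gene_id %in% gene_set), .groups = "drop")
  if (nrow(out) == 0 || any(out$K == 0)) {
    abort("degenerate enrichment: empty category within the universe")
  }
  kk <- if (ease) pmax(out$k - 1L, 0L) else out$k
  out %>%
    mutate(
      n = n, N = N,
      fold = (.data$k / n) / (.data$K / N),
      p = phyper(kk - 1L, .data$K, N - .data$K, n, lower.tail = FALSE),
      p_adj = p.adjust(.data$p, method = "BH")
    ) %>%
    select("category", "k", "n", "K", "N", "fold", "p", "p_adj") %>%
    arrange(.data$p)
}

#' Region density around gene 5' ends
#'
#' Bins region midpoints by signed, strand-aware distance to every gene TSS
#' within `+/- window` bp, aggregated over genes. Negative distances are
#' upstream of the TSS.
#'
#' @param map Region map tibble.
#' @param genes Gene tibble (`chrom`, `strand`, `tss`).
#' @param window Half-window around each TSS in bp (default 50,000).
#' @param bin Bin width in bp (default 1,000); must divide `window`.
#' @return A `regmap_tss_profile` tibble: `bin_start` (signed left edge),
#'   `bin_mid`, `count`. The bin `[0, bin)` starts exactly at the TSS.
#' @export
tss_distance_profile <- function(map, genes, window = 50000L, bin = 1000L) {
  if (window %% bin != 0) abort("window must be a multiple of bin")
  edges <- seq(-window, window, by = bin)
  counts <- integer(length(edges) - 1)
  if (nrow(map) > 0 && nrow(genes) > 0) {
    mid <- (map$start + map$end) %/% 2L
    mid_gr <- GenomicRanges::GRanges(map$chrom,
                                     IRanges::IRanges(mid + 1L, width = 1L))
    win_gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(genes$tss - window, 0L) + 1L,
                       genes$tss + window))
    hits <- GenomicRanges::findOverlaps(win_gr, mid_gr)
    gi <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    signed <- if_else(genes$strand[gi] == "+",
                      as.numeric(mid[ri] - genes$tss[gi]),
                      as.numeric(genes$tss[gi] - mid[ri]))
    signed <- signed[signed >= -window & signed < window]
    idx <- floor(signed / bin) + window %/% bin + 1L
    tab <- tabulate(idx, nbins = length(counts))
    counts <- as.integer(tab)
  }
  structure(
    tibble(bin_start = edges[-length(edges)],
           bin_mid = edges[-length(edges)] + bin / 2,
           count = counts),
    class = c("regmap_tss_profile", class(tibble())))
}
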