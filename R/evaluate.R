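# Recovery metrics used to validate the pipeline against planted truth.

#' Recall and precision of a region map against planted elements
#'
#' Recall is the fraction of planted elements overlapped (>= 1 bp) by at
#' least one retained region; precision is the fraction of retained regions
#' overlapping at least one planted element.
#'
#' @param map Region map tibble.
#' @param elements Planted-element tibble.
#' @return One-row tibble: `n_regions`, `n_elements`, `recall`, `precision`.
#' @export
recovery_metrics <- function(map, elements) {
  tibble(
    n_regions = nrow(map),
    n_elements = nrow(elements),
    recall = overlap_fraction(elements, map),
    precision = overlap_fraction(map, elements)
  )
}

#' Jaccard index of two gene sets
#'
#' @param a,b Character vectors of gene ids.
#' @return `|intersect| / |union|` (1 when both sets are empty).
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}
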