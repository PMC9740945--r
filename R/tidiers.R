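# broom-style tidiers for the package's result objects.

#' Tidy a rank-sum result
#'
#' @param x A `regmap_ranksum` object.
#' @param ... Unused.
#' @return The per-group box descriptors as a tibble.
#' @method tidy regmap_ranksum
#' @export
tidy.regmap_ranksum <- function(x, ...) x$summary

#' @rdname tidy.regmap_ranksum
#' @method glance regmap_ranksum
#' @export
glance.regmap_ranksum <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, n1 = x$n1, n2 = x$n2,
         p_two_sided = x$p_two_sided, method = x$method)
}

#' Tidy an enrichment result
#'
#' @param x A `regmap_enrichment` object.
#' @param ... Unused.
#' @return One row per matched-random replicate (`replicate`,
#'   `null_fraction`).
#' @method tidy regmap_enrichment
#' @export
tidy.regmap_enrichment <- function(x, ...) {
  tibble(replicate = seq_along(x$null_fractions),
         null_fraction = x$null_fractions)
}

#' @rdname tidy.regmap_enrichment
#' @method glance regmap_enrichment
#' @export
glance.regmap_enrichment <- function(x, ...) {
  tibble(track = x$track_name, n_regions = x$n_regions,
         observed_fraction = x$observed_fraction, null_mean = x$null_mean,
         ratio = x$ratio, empirical_p = x$empirical_p,
         n_replicates = x$n_replicates)
}

#' Tidy a score-colocalization result
#'
#' @param x A `regmap_colocalization` object.
#' @param ... Unused.
#' @return The per-peak score/overlap tibble.
#' @method tidy regmap_colocalization
#' @export
tidy.regmap_colocalization <- function(x, ...) x$scores

#' @rdname tidy.regmap_colocalization
#' @method glance regmap_colocalization
#' @export
glance.regmap_colocalization <- function(x, ...) {
  glance(x$test)
}
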