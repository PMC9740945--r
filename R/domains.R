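# GREAT-style basal+extension regulatory domains, region->gene association,
# proximal/distal classification, and the P/D1/D2 gene partition.

#' Build basal+extension regulatory domains
#'
#' Each gene receives a basal domain around its TSS (`up` bp upstream, `down`
#' bp downstream, strand-aware) which is then extended in both directions to
#' the nearer of (a) the nearest other gene's basal-domain boundary, (b)
#' `TSS +/- max_ext`, and (c) the chromosome end. Basal domains are never
#' truncated, even when neighbouring basal domains overlap.
#'
#' @param genes Gene tibble from [read_gene_annotation()] (`gene_id`, `chrom`,
#'   `strand`, `tss`).
#' @param genome Genome tibble (`chrom`, `size`).
#' @param up,down Basal extent upstream/downstream of the TSS in bp
#'   (defaults 2000/2000).
#' @param max_ext Maximum extension from the TSS in bp (default 500,000).
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `strand`, `tss`,
#'   `basal_start`, `basal_end`, `ext_start`, `ext_end` (0-based half-open).
#' @export
build_domains <- function(genes, genome, up = 2000L, down = 2000L,
                          max_ext = 500000L) {
  stopifnot(up >= 0, down >= 0, max_ext >= max(up, down))
  sizes <- setNames(genome$size, genome$chrom)
  unknown <- setdiff(unique(genes$chrom), names(sizes))
  if (length(unknown) > 0) {
    abort(paste0("gene chromosome(s) absent from genome: ",
                 paste(unknown, collapse = ", ")))
  }
  d <- genes %>%
    mutate(
      size = sizes[.data$chrom],
      # basal window as a half-open span around the TSS, mirrored on the
      # minus strand: [tss - up, tss + down) for "+", [tss - down, tss + up)
      # for "-" (symmetric at the +/-2 kb defaults)
      basal_start = if_else(.data$strand == "+",
                            .data$tss - up, .data$tss - down),
      basal_end = if_else(.data$strand == "+",
                          .data$tss + down, .data$tss + up),
      basal_start = pmax(.data$basal_start, 0L),
      basal_end = pmin(.data$basal_end, .data$size)
    )
  if (any(d$basal_end <= 0 | d$basal_start >= d$size)) {
    abort("basal window falls entirely outside its chromosome")
  }
  d <- d %>%
    group_by(.data$chrom) %>%
    arrange(.data$tss, .by_group = TRUE) %>%
    mutate(
      left_nb = cummax_lag(.data$basal_end),
      right_nb = cummin_lead(.data$basal_start)
    ) %>%
    ungroup() %>%
    mutate(
      ext_start = pmax(.data$tss - max_ext, .data$left_nb, 0L),
      ext_end = pmin(.data$tss + max_ext, .data$right_nb, .data$size),
      # the basal domain is never truncated by a neighbour
      ext_start = pmin(.data$ext_start, .data$basal_start),
      ext_end = pmax(.data$ext_end, .data$basal_end)
    ) %>%
    arrange(.data$chrom, .data$tss) %>%
    select("gene_id", "chrom", "strand", "tss", "basal_start", "basal_end",
           "ext_start", "ext_end")
  d
}

# running max of basal_end over genes strictly before each row (-Inf-capped),
# and running min of basal_start over genes strictly after each row
cummax_lag <- function(x) {
  n <- length(x)
  if (n == 1) return(-Inf)
  c(-Inf, cummax(x)[-n])
}
cummin_lead <- function(x) {
  n <- length(x)
  if (n == 1) return(Inf)
  rev(c(Inf, cummin(rev(x))[-n]))
}

#' Associate regions with genes through regulatory domains
#'
#' A region associates with every gene whose extended regulatory domain
#' contains the region midpoint. The signed distance runs from the gene TSS
#' to the midpoint, negative upstream of the TSS (strand-aware). Midpoints
#' within +/- `proximal_max` bp of the TSS are proximal; midpoints between
#' `proximal_max` and `distal_max` bp are distal; beyond `distal_max` no
#' association is made.
#'
#' @param map Region map tibble (needs `region_id`; one is derived from the
#'   row order if absent).
#' @param domains Domain tibble from [build_domains()].
#' @param overlap_mode `"midpoint"` (default: midpoint containment) or
#'   `"any"` (>= 1 bp overlap between region and extended domain; distance
#'   still measured TSS-to-midpoint).
#' @param proximal_max,distal_max Class boundaries in bp (defaults 2000 and
#'   500,000, boundary-inclusive).
#' @return Tibble of associations: `region_id`, `gene_id`,
#'   `signed_distance`, `klass` (`"proximal"`/`"distal"`).
#' @export
associate_regions <- function(map, domains,
                              overlap_mode = c("midpoint", "any"),
                              proximal_max = 2000L, distal_max = 500000L) {
  overlap_mode <- match.arg(overlap_mode)
  map <- as_tibble(map)
  if (!"region_id" %in% names(map)) {
    map$region_id <- sprintf("region_%05d", seq_len(nrow(map)))
  }
  if (nrow(map) == 0 || nrow(domains) == 0) {
    return(tibble(region_id = character(), gene_id = character(),
                  signed_distance = numeric(), klass = character()))
  }
  mid <- (map$start + map$end) %/% 2L
  dom_gr <- GenomicRanges::GRanges(
    domains$chrom,
    IRanges::IRanges(domains$ext_start + 1L, domains$ext_end))
  q_gr <- if (overlap_mode == "midpoint") {
    GenomicRanges::GRanges(map$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  } else {
    GenomicRanges::GRanges(map$chrom, IRanges::IRanges(map$start + 1L, map$end))
  }
  hits <- GenomicRanges::findOverlaps(q_gr, dom_gr, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  signed <- if_else(domains$strand[si] == "+",
                    as.numeric(mid[qi] - domains$tss[si]),
                    as.numeric(domains$tss[si] - mid[qi]))
  out <- tibble(
    region_id = map$region_id[qi],
    gene_id = domains$gene_id[si],
    signed_distance = signed,
    klass = if_else(abs(signed) <= proximal_max, "proximal", "distal")
  ) %>%
    filter(abs(.data$signed_distance) <= distal_max) %>%
    distinct() %>%
    arrange(.data$gene_id, .data$signed_distance)
  out
}

#' Partition genes into P / D1 / D2 groups
#'
#' Counts, per gene, the distinct proximal and distal regions associated with
#' it, and derives group membership: `P` (>= 1 proximal region), `D1` (1-2
#' distal regions), `D2` (>= 3 distal regions). `P` may intersect `D1`/`D2`;
#' `D1` and `D2` are disjoint and their union is the distal (`D`) gene set.
#'
#' @param associations Association tibble from [associate_regions()].
#' @return Tibble with one row per associated gene: `gene_id`, `n_proximal`,
#'   `n_distal`, logical `P`, `D1`, `D2`, and `group` (the distal-based label
#'   `"D2"`, `"D1"`, or `"P_only"`).
#' @export
partition_genes <- function(associations) {
  if (nrow(associations) == 0) {
    return(tibble(gene_id = character(), n_proximal = integer(),
                  n_distal = integer(), P = logical(), D1 = logical(),
                  D2 = logical(), group = character()))
  }
  associations %>%
    distinct(.data$gene_id, .data$region_id, .data$klass) %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_proximal = n_distinct(.data$region_id[.data$klass == "proximal"]),
      n_distal = n_distinct(.data$region_id[.data$klass == "distal"]),
      .groups = "drop"
    ) %>%
    mutate(
      P = .data$n_proximal >= 1L,
      D1 = .data$n_distal >= 1L & .data$n_distal <= 2L,
      D2 = .data$n_distal >= 3L,
      group = case_when(.data$D2 ~ "D2", .data$D1 ~ "D1", TRUE ~ "P_only")
    )
}

#' Region-level summary of associations
#'
#' A region counts as proximal if it has at least one proximal association
#' and as distal if it has at least one distal association (the two are not
#' exclusive). `n_genes` reports how many different genes each region is
#' associated with.
#'
#' @param associations Association tibble from [associate_regions()].
#' @return Tibble `region_id`, `n_genes`, `is_proximal`, `is_distal`.
#' @export
summarize_regions <- function(associations) {
  if (nrow(associations) == 0) {
    return(tibble(region_id = character(), n_genes = integer(),
                  is_proximal = logical(), is_distal = logical()))
  }
  associations %>%
    group_by(.data$region_id) %>%
    summarise(
      n_genes = n_distinct(.data$gene_id),
      is_proximal = any(.data$klass == "proximal"),
      is_distal = any(.data$klass == "distal"),
      .groups = "drop"
    )
}
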