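# Deterministic synthetic-data generator: a toy genome with planted
# regulatory elements, weight-proportional selected fragment libraries
# emitted as paired-end SAM, an H3K27ac-like scored peak track, and an
# expression table in which genes carrying many distal elements are boosted.
# Everything is a pure function of the configuration (seed included).

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic dataset. The whole
#' dataset is a deterministic function of this configuration; each generator
#' stage derives its own stream from `seed` so stages can be re-run
#' independently.
#'
#' @param seed Integer master seed (default 17).
#' @param n_chroms Number of chromosomes (default 3).
#' @param chrom_length Length of each chromosome in bp (default 10 Mb).
#' @param n_genes Number of genes (default 300), spread evenly over
#'   chromosomes with jittered positions and random strands.
#' @param n_elements Number of planted regulatory elements (default 200).
#' @param element_length_range Element length range in bp (default 300-900,
#'   uniform).
#' @param fragment_length_mean,fragment_length_sd,fragment_length_min
#'   Cloned-fragment length model: normal, mean 750 bp, sd 100, truncated at
#'   200 bp.
#' @param n_fragments Fragments per library (default 100,000). At this
#'   default a single fragment corresponds to exactly RPM 10, i.e. sits at
#'   (and is excluded by) the strict RPM threshold.
#' @param background_fraction Fraction of fragments drawn uniformly from the
#'   genome instead of from planted elements (default 0.10).
#' @param n_libraries Number of replicate libraries (default 2).
#' @param d2_fraction Fraction of genes intended to carry >= 3 distal
#'   elements (default 0.1).
#' @param d2_elements Distal elements planted per intended-D2 gene
#'   (default 3).
#' @param proximal_fraction Fraction of elements planted proximally (within
#'   +/- 1 kb of a gene TSS; default 0.25).
#' @param distal_range Distance range (bp, midpoint to TSS) for distal
#'   element placement (default 5,000-45,000; safely inside the 2 kb-500 kb
#'   classification band).
#' @param element_weight_sdlog Log-sd of the log-normal per-element sampling
#'   weights (median weight 1).
#' @param decoy_fraction Fraction of track peaks containing no planted
#'   element (default 0.2).
#' @param peak_pad Padding of the scored peak around its element in bp
#'   (default 200).
#' @param jitter_sd Sd (bp) of the fragment-centre jitter around the element
#'   midpoint (default 100).
#' @param read_length Read length for the emitted pairs (default 150 bp).
#' @param corrupt_fraction Fraction of pairs emitted corrupted (secondary
#'   flag, MAPQ below threshold, or orphaned) to exercise the filters;
#'   default 0.
#' @param expr_meanlog,expr_sdlog Log-normal baseline of the FPKM table
#'   (defaults 1 and 1).
#' @param d2_effect Multiplier applied to the FPKM of intended-D2 genes
#'   (default 4; 1 gives the null dataset).
#' @return A validated `regmap_sim_config` list.
#' @export
sim_config <- function(seed = 17L,
                       n_chroms = 3L,
                       chrom_length = 1e7,
                       n_genes = 300L,
                       n_elements = 200L,
                       element_length_range = c(300L, 900L),
                       fragment_length_mean = 750,
                       fragment_length_sd = 100,
                       fragment_length_min = 200L,
                       n_fragments = 1e5,
                       background_fraction = 0.10,
                       n_libraries = 2L,
                       d2_fraction = 0.1,
                       d2_elements = 3L,
                       proximal_fraction = 0.25,
                       distal_range = c(5000L, 45000L),
                       element_weight_sdlog = 1,
                       decoy_fraction = 0.2,
                       peak_pad = 200L,
                       jitter_sd = 100,
                       read_length = 150L,
                       corrupt_fraction = 0,
                       expr_meanlog = 1,
                       expr_sdlog = 1,
                       d2_effect = 4) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chroms, cfg$chrom_length, cfg$n_genes, cfg$n_elements,
              cfg$n_fragments, cfg$n_libraries)
  if (any(counts <= 0)) abort("all counts must be positive")
  fracs <- c(cfg$background_fraction, cfg$d2_fraction, cfg$proximal_fraction,
             cfg$decoy_fraction, cfg$corrupt_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  n_d2 <- round(cfg$d2_fraction * cfg$n_genes)
  if (n_d2 * cfg$d2_elements + round(cfg$proximal_fraction * cfg$n_elements) >
      cfg$n_elements) {
    abort("element budget too small for the requested D2/proximal structure")
  }
  structure(cfg, class = "regmap_sim_config")
}

#' Simulate the genome and gene annotation
#'
#' Places genes on an evenly spaced, jittered grid so that basal windows
#' (+/- 2 kb) can never overlap, with random strands and gene lengths of
#' 5-20 kb.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (chrom sizes tibble) and `genes` (gene tibble
#'   with `tss`/`tes`).
#' @export
sim_genome <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  genome <- tibble(chrom = paste0("chr", seq_len(config$n_chroms)),
                   size = as.integer(config$chrom_length))
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1)))
  margin <- 60000
  genes <- purrr::map2(genome$chrom, per_chrom, function(chrom, n) {
    if (n == 0) return(NULL)
    spacing <- (config$chrom_length - 2 * margin) / n
    if (spacing < 10000) {
      abort("gene density infeasible: genes would be closer than 10 kb")
    }
    tss <- as.integer(round(
      margin + (seq_len(n) - 0.5) * spacing +
        runif(n, -spacing / 5, spacing / 5)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    glen <- as.integer(round(runif(n, 5000, 20000)))
    tibble(chrom = chrom, strand = strand, tss = tss,
           start = if_else(strand == "+", tss,
                           pmax(tss - glen, 0L)),
           end = if_else(strand == "+",
                         pmin(tss + glen, as.integer(config$chrom_length)),
                         tss + 1L))
  }) %>% bind_rows()
  genes <- genes %>%
    mutate(gene_id = sprintf("g%03d", row_number()),
           tes = if_else(.data$strand == "+", .data$end - 1L, .data$start)) %>%
    select("gene_id", "chrom", "strand", "start", "end", "tss", "tes")
  list(genome = genome, genes = genes)
}

#' Plant regulatory elements and build the scored peak track
#'
#' Assigns elements to genes to realise the configured structure: intended-D2
#' genes receive `d2_elements` distal elements (split across both sides of
#' the TSS), further genes receive 1-2 distal elements, and a configured
#' fraction of elements sit proximally (within +/- 1 kb of a TSS). Placement
#' is rejection-sampled so that (i) element midpoints stay >= 5 kb apart
#' (their called regions cannot merge) and (ii) no gene other than an
#' intended-D2 target is exposed to 3 or more planted distal elements --
#' an element between two genes legitimately falls into both flanking
#' regulatory domains, and this bookkeeping keeps the intended-D2 set exactly
#' the configured targets. Each element emits a surrounding scored peak
#' (score proportional to its sampling weight); decoy peaks with lower scores
#' and no element are added on top.
#'
#' @param genome,genes Output of [sim_genome()].
#' @param config A [sim_config()].
#' @return List: `elements` (element tibble with `weight`, `target_gene`,
#'   `intended_klass`), `gene_truth` (per-gene intended counts and group),
#'   `track` (scored peak tibble with `name` and `score`), `domains` (the
#'   regulatory domains used for the intended bookkeeping).
#' @export
sim_plant_elements <- function(genome, genes, config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  domains <- build_domains(genes, genome)
  sizes <- setNames(genome$size, genome$chrom)

  n_d2 <- round(config$d2_fraction * config$n_genes)
  n_prox <- round(config$proximal_fraction * config$n_elements)
  n_d1_elem <- config$n_elements - n_d2 * config$d2_elements - n_prox

  dom_by_chrom <- split(domains, domains$chrom)
  # per-chromosome TSS rank, used to keep intended-D2 targets spread out
  gene_rank <- genes %>%
    group_by(.data$chrom) %>%
    arrange(.data$tss, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup()

  # intended-D2 targets are sampled with >= 2 genes between any two on the
  # same chromosome, so no gene sits in the spillover zone of two targets
  pick_d2 <- function() {
    for (min_gap in c(3L, 2L, 1L)) {
      picked <- character(0)
      for (g in sample(gene_rank$gene_id)) {
        i <- match(g, gene_rank$gene_id)
        same <- gene_rank$gene_id %in% picked &
          gene_rank$chrom == gene_rank$chrom[i] &
          abs(gene_rank$rank - gene_rank$rank[i]) < min_gap
        if (!any(same)) picked <- c(picked, g)
        if (length(picked) == n_d2) return(picked)
      }
    }
    sample(gene_rank$gene_id, n_d2)
  }

  plant_once <- function() {
    d2_genes <- pick_d2()
    exposure <- setNames(integer(nrow(genes)), genes$gene_id)
    placed_mid <- list()
    elements <- list()

    distal_exposed <- function(chrom, mid) {
      d <- dom_by_chrom[[chrom]]
      signed <- if_else(d$strand == "+", mid - d$tss, d$tss - mid)
      hit <- d$ext_start <= mid & mid < d$ext_end &
        abs(signed) > 2000 & abs(signed) <= 500000
      d$gene_id[hit]
    }

    # try to place one element for the given target; TRUE on success
    try_place <- function(gene_id, klass, tries = 100L) {
      g <- genes[match(gene_id, genes$gene_id), ]
      for (try in seq_len(tries)) {
        len <- as.integer(round(runif(1, config$element_length_range[1],
                                      config$element_length_range[2])))
        if (klass == "proximal") {
          mid <- g$tss + as.integer(round(runif(1, -1000, 1000)))
        } else {
          side <- sample(c(-1L, 1L), 1)
          off <- as.integer(round(runif(1, config$distal_range[1],
                                        config$distal_range[2])))
          mid <- g$tss + side * off
        }
        if (mid - len %/% 2 < 0 || mid + len %/% 2 >= sizes[g$chrom]) next
        near <- placed_mid[[g$chrom]]
        # midpoints >= 5 kb apart so called regions cannot merge
        if (!is.null(near) && any(abs(near - mid) < 5000)) next
        exposed <- distal_exposed(g$chrom, mid)
        capped <- setdiff(exposed, d2_genes)
        if (any(exposure[capped] + 1L > 2L)) next
        if (klass == "distal" && !(gene_id %in% exposed)) next
        exposure[exposed] <<- exposure[exposed] + 1L
        placed_mid[[g$chrom]] <<- c(near, mid)
        elements[[length(elements) + 1L]] <<- tibble(
          chrom = g$chrom, start = mid - len %/% 2L,
          end = mid - len %/% 2L + len,
          target_gene = gene_id, intended_klass = klass
        )
        return(TRUE)
      }
      FALSE
    }

    # phase 1: the configured distal load of every intended-D2 gene
    for (g in d2_genes) {
      for (k in seq_len(config$d2_elements)) {
        if (!try_place(g, "distal")) {
          abort(sprintf("could not place a distal element for D2 gene %s", g))
        }
      }
    }
    # phase 2: proximal elements on genes picked as needed
    prox_pool <- sample(setdiff(genes$gene_id, d2_genes))
    placed <- 0L
    for (g in prox_pool) {
      if (placed >= n_prox) break
      if (try_place(g, "proximal", tries = 30L)) placed <- placed + 1L
    }
    if (placed < n_prox) {
      abort("could not place the requested proximal elements")
    }
    # phase 3: remaining distal elements on genes still under the D1 cap
    placed <- 0L
    guard <- 0L
    while (placed < n_d1_elem) {
      guard <- guard + 1L
      if (guard > 50L * max(n_d1_elem, 1L)) {
        abort("could not place the requested distal elements within 500 kb")
      }
      open <- names(exposure)[exposure <= 1L]
      open <- setdiff(open, d2_genes)
      if (length(open) == 0) abort("no gene left under the distal cap")
      g <- sample(open, 1)
      if (try_place(g, "distal", tries = 30L)) placed <- placed + 1L
    }
    bind_rows(elements)
  }

  # rejection-restart: a fresh target draw on the rare unplaceable layout
  elements <- NULL
  for (attempt in 1:10) {
    elements <- tryCatch(plant_once(), error = function(e) e)
    if (!inherits(elements, "error")) break
  }
  if (inherits(elements, "error")) stop(elements)

  elements <- elements %>%
    mutate(element_id = sprintf("el_%03d", row_number()),
           weight = rlnorm(dplyr::n(), 0, config$element_weight_sdlog)) %>%
    select("element_id", "chrom", "start", "end", "weight",
           "target_gene", "intended_klass")

  # intended per-gene structure: associate element midpoints with domains
  intended <- associate_regions(
    elements %>% rename(region_id = "element_id"), domains)
  gene_truth <- partition_genes(intended) %>%
    rename(intended_n_proximal = "n_proximal",
           intended_n_distal = "n_distal") %>%
    mutate(intended_group = .data$group) %>%
    select("gene_id", "intended_n_proximal", "intended_n_distal",
           "intended_group")
  gene_truth <- genes %>%
    select("gene_id") %>%
    left_join(gene_truth, by = "gene_id") %>%
    mutate(intended_n_proximal = dplyr::coalesce(.data$intended_n_proximal, 0L),
           intended_n_distal = dplyr::coalesce(.data$intended_n_distal, 0L),
           intended_group = dplyr::coalesce(.data$intended_group, "none"))

  # scored peaks: one per element plus low-score decoys overlapping nothing
  peaks <- elements %>%
    mutate(chrom = .data$chrom,
           start = pmax(.data$start - config$peak_pad, 0L),
           end = pmin(.data$end + config$peak_pad,
                      as.integer(sizes[.data$chrom])),
           name = paste0("peak_", .data$element_id),
           score = round(100 * .data$weight, 1)) %>%
    select("chrom", "start", "end", "name", "score")
  n_decoy <- round(config$decoy_fraction / (1 - config$decoy_fraction) *
                     nrow(elements))
  decoys <- vector("list", n_decoy)
  el_gr <- as_gr(elements, use_strand = FALSE)
  for (i in seq_len(n_decoy)) {
    for (try in 1:200) {
      chrom <- sample(genome$chrom, 1, prob = genome$size)
      len <- as.integer(round(runif(1, 500, 1500)))
      start <- as.integer(floor(runif(1) * (sizes[chrom] - len)))
      cand <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(start + 1L, width = len))
      if (GenomicRanges::countOverlaps(cand, el_gr) == 0) {
        decoys[[i]] <- tibble(chrom = chrom, start = start, end = start + len,
                              name = sprintf("decoy_%03d", i),
                              score = round(100 * rlnorm(1, -1.5, 0.5), 1))
        break
      }
    }
  }
  track <- bind_rows(peaks, bind_rows(decoys)) %>%
    arrange(.data$chrom, .data$start)

  list(elements = elements, gene_truth = gene_truth, track = track,
       domains = domains)
}

#' Simulate one selected-fragment library as paired-end SAM
#'
#' Models reporter-based selection as weight-proportional sampling of
#' fragments from the planted elements: a `1 - background_fraction` share of
#' fragments is centred (with jitter) on a sampled element, the rest is
#' uniform background. Every fragment emits one proper read pair with flag
#' combination 99/147 (plus chain) or 83/163 (minus chain), MAPQ 42 and
#' consistent POS/PNEXT/TLEN; a configured fraction of pairs is corrupted
#' (secondary flag, low MAPQ, or orphaned mate) to exercise the filters.
#'
#' @param truth Output of [sim_plant_elements()].
#' @param genome Genome tibble.
#' @param config A [sim_config()].
#' @param library_index 1-based library number (drives the RNG stream).
#' @param library_id Library label (default `L<library_index>`).
#' @param path Optional output path; when given, SAM text is written there.
#' @return Invisibly when `path` is given, otherwise a character vector of
#'   SAM lines. The attribute `fragments` carries the generating fragment
#'   tibble (the ground truth for recovery checks).
#' @export
sim_library <- function(truth, genome, config, library_index = 1L,
                        library_id = paste0("L", library_index),
                        path = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 100L + library_index)
  sizes <- setNames(genome$size, genome$chrom)
  n <- as.integer(config$n_fragments)
  n_bg <- as.integer(round(config$background_fraction * n))
  n_el <- n - n_bg

  len <- as.integer(pmax(config$fragment_length_min,
                         round(rnorm(n, config$fragment_length_mean,
                                     config$fragment_length_sd))))
  el_idx <- sample.int(nrow(truth$elements), n_el, replace = TRUE,
                       prob = truth$elements$weight)
  el_mid <- (truth$elements$start[el_idx] + truth$elements$end[el_idx]) %/% 2L
  mid <- el_mid + as.integer(round(rnorm(n_el, 0, config$jitter_sd)))
  el_chrom <- truth$elements$chrom[el_idx]
  bg_chrom <- sample(genome$chrom, n_bg, replace = TRUE, prob = genome$size)
  chrom <- c(el_chrom, bg_chrom)
  start <- integer(n)
  start[seq_len(n_el)] <- mid - len[seq_len(n_el)] %/% 2L
  bg_i <- n_el + seq_len(n_bg)
  start[bg_i] <- as.integer(floor(runif(n_bg) * (sizes[bg_chrom] - len[bg_i] + 1)))
  start <- pmax(start, 0L)
  start <- pmin(start, as.integer(sizes[chrom]) - len)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  frag <- tibble(chrom = chrom, start = start, end = start + len,
                 strand = strand,
                 qname = sprintf("%s:f%06d", library_id, seq_len(n)),
                 origin = c(truth$elements$element_id[el_idx],
                            rep("background", n_bg)))
  rl <- pmin(config$read_length, len)
  left_pos1 <- frag$start + 1L              # SAM 1-based leftmost
  right_pos1 <- frag$end - rl + 1L
  plus <- frag$strand == "+"
  # plus chain: 99 at left mate, 147 at right; minus chain: 163 left, 83 right
  flag_left <- if_else(plus, 99L, 163L)
  flag_right <- if_else(plus, 147L, 83L)
  mapq <- rep(42L, n)
  keep_right <- rep(TRUE, n)
  if (config$corrupt_fraction > 0) {
    bad <- which(runif(n) < config$corrupt_fraction)
    type <- sample(c("secondary", "lowmapq", "orphan"), length(bad),
                   replace = TRUE)
    flag_left[bad[type == "secondary"]] <-
      flag_left[bad[type == "secondary"]] + 256L
    flag_right[bad[type == "secondary"]] <-
      flag_right[bad[type == "secondary"]] + 256L
    mapq[bad[type == "lowmapq"]] <- 3L
    keep_right[bad[type == "orphan"]] <- FALSE
  }
  cigar <- sprintf("%dM", rl)
  rec_left <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                      frag$qname, flag_left, frag$chrom, left_pos1, mapq,
                      cigar, right_pos1, frag$end - frag$start)
  rec_right <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                       frag$qname, flag_right, frag$chrom, right_pos1, mapq,
                       cigar, left_pos1, -(frag$end - frag$start))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, genome$size))
  body <- character(2L * n)
  body[seq(1L, 2L * n, by = 2L)] <- rec_left
  body[seq(2L, 2L * n, by = 2L)] <- rec_right
  keep <- rep(TRUE, 2L * n)
  keep[seq(2L, 2L * n, by = 2L)] <- keep_right
  sam <- c(header, body[keep])
  attr(sam, "fragments") <- frag
  if (!is.null(path)) {
    readr::write_lines(sam, path)
    return(invisible(structure(path, fragments = frag)))
  }
  sam
}

#' Simulate the expression table and gene categories
#'
#' Baseline FPKM is log-normal; intended-D2 genes are multiplied by the
#' configured effect (multiplier 1 gives the exchangeable null). Three
#' categories are emitted: `cancer_like` (enriched among intended-D2 genes),
#' `housekeeping_like` (enriched among genes with intended proximal
#' elements), and `neutral`.
#'
#' @param truth Output of [sim_plant_elements()].
#' @param genes Gene tibble.
#' @param config A [sim_config()].
#' @return List with `expression` (tibble `gene_id`, `fpkm`) and
#'   `categories` (long tibble `gene_id`, `category`).
#' @export
sim_expression <- function(truth, genes, config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 200L)
  gt <- truth$gene_truth[match(genes$gene_id, truth$gene_truth$gene_id), ]
  fpkm <- rlnorm(nrow(genes), config$expr_meanlog, config$expr_sdlog)
  is_d2 <- gt$intended_group == "D2"
  fpkm[is_d2] <- fpkm[is_d2] * config$d2_effect
  expression <- tibble(gene_id = genes$gene_id, fpkm = fpkm)
  p_cancer <- if_else(is_d2, 0.6, 0.05)
  p_house <- if_else(gt$intended_n_proximal >= 1, 0.6, 0.05)
  categories <- bind_rows(
    tibble(gene_id = genes$gene_id[runif(nrow(genes)) < p_cancer],
           category = "cancer_like"),
    tibble(gene_id = genes$gene_id[runif(nrow(genes)) < p_house],
           category = "housekeeping_like"),
    tibble(gene_id = genes$gene_id[runif(nrow(genes)) < 0.15],
           category = "neutral")
  )
  list(expression = expression, categories = categories)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs all generator stages and writes the standard file set: `genome.tsv`,
#' `genes.gff3`, `h3k27ac.bed` (scored peaks), `elements.bed` (planted
#' truth), one SAM per library (`L1.sam`, ...), `fpkm.tsv`,
#' `categories.tsv`, and `gene_truth.tsv`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return List with the in-memory objects (`genome`, `genes`, `truth`,
#'   `expression`, `categories`) and a `paths` list of everything written.
#' @export
simulate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gg <- sim_genome(config)
  truth <- sim_plant_elements(gg$genome, gg$genes, config)
  expr <- sim_expression(truth, gg$genes, config)
  paths <- list(
    genome = file.path(dir, "genome.tsv"),
    genes = file.path(dir, "genes.gff3"),
    track = file.path(dir, "h3k27ac.bed"),
    elements = file.path(dir, "elements.bed"),
    expression = file.path(dir, "fpkm.tsv"),
    categories = file.path(dir, "categories.tsv"),
    gene_truth = file.path(dir, "gene_truth.tsv"),
    sam = file.path(dir, paste0("L", seq_len(config$n_libraries), ".sam"))
  )
  write_genome(gg$genome, paths$genome)
  write_gene_annotation(gg$genes, paths$genes)
  write_bed(truth$track, paths$track)
  write_bed(truth$elements %>%
              mutate(name = .data$element_id, score = .data$weight) %>%
              select("chrom", "start", "end", "name", "score"),
            paths$elements)
  readr::write_tsv(expr$expression, paths$expression)
  readr::write_tsv(expr$categories, paths$categories)
  readr::write_tsv(truth$gene_truth, paths$gene_truth)
  for (i in seq_len(config$n_libraries)) {
    sim_library(truth, gg$genome, config, library_index = i,
                path = paths$sam[i])
  }
  list(genome = gg$genome, genes = gg$genes, truth = truth,
       expression = expr$expression, categories = expr$categories,
       paths = paths)
}
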