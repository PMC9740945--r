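# Rank-sum tests, composition percentages, fold enrichment, TSS profile.

test_that("the exact rank-sum test matches enumeration on the canonical example", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), fpkm_min = -Inf)
  expect_equal(r$u_statistic, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_two_sided, 0.1)   # 2/20 rank assignments as extreme

  o <- oracle_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, o$u)
  expect_equal(r$p_two_sided, o$p)
})

test_that("identical samples give p = 1 and the cutoff can empty a group", {
  x <- c(1, 2, 3, 4)
  r <- rank_sum_test(x, x, fpkm_min = -Inf)
  expect_equal(r$p_two_sided, 1)
  expect_error(rank_sum_test(c(0.1, 0.2), c(1, 2, 3), fpkm_min = 0.5),
               "degenerate")
  # cutoff removes values below, keeps values at/above
  r2 <- rank_sum_test(c(0.4, 0.5, 3), c(1, 2), fpkm_min = 0.5)
  expect_equal(r2$n1, 2L)
})

test_that("U statistics of the two orientations sum to n1*n2", {
  set.seed(14)
  for (rep in 1:20) {
    a <- round(rlnorm(sample(3:12, 1)), 4)
    b <- round(rlnorm(sample(3:12, 1)), 4)
    ra <- rank_sum_test(a, b, fpkm_min = -Inf)
    rb <- rank_sum_test(b, a, fpkm_min = -Inf)
    expect_equal(ra$u_statistic + rb$u_statistic, ra$n1 * ra$n2)
  }
})

test_that("exact and normal-approximation p agree closely at n = 8 per group", {
  set.seed(25)
  for (rep in 1:20) {
    a <- rlnorm(8); b <- rlnorm(8, meanlog = 0.5)
    pe <- rank_sum_test(a, b, fpkm_min = -Inf, exact_max = 8)$p_two_sided
    pn <- rank_sum_test(a, b, fpkm_min = -Inf, exact_max = 0)$p_two_sided
    expect_lte(abs(pe - pn), 0.02)
  }
})

test_that("group composition reports percentages and tolerates overlapping categories", {
  groups <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    P = TRUE, D1 = FALSE, D2 = c(rep(TRUE, 4), rep(FALSE, 6))
  )
  cats <- tibble::tibble(
    gene_id = c(sprintf("g%02d", 1:4), sprintf("g%02d", 1:10)),
    category = c(rep("cancer", 4), rep("all", 10))
  )
  comp <- group_composition(groups, cats, group_cols = c("P", "D2"))
  expect_equal(comp$percent[comp$group == "P" & comp$category == "cancer"], 40)
  expect_equal(comp$percent[comp$group == "D2" & comp$category == "cancer"], 100)
  # overlapping categories may sum beyond 100% within a group
  expect_gt(sum(comp$percent[comp$group == "P"]), 100)
  expect_equal(comp$percent[comp$group == "P" & comp$category == "all"], 100)
  groups$D1 <- FALSE
  expect_error(group_composition(groups, cats, group_cols = "D1"), "empty")
})

test_that("fold enrichment matches the direct hypergeometric summation", {
  universe <- sprintf("g%03d", 1:100)
  category <- tibble::tibble(gene_id = universe[1:10], category = "cat")
  gene_set <- c(universe[1:6], universe[11:24])   # k = 6 of n = 20
  fe <- fold_enrichment(gene_set, category, universe)
  expect_equal(fe$fold, 3.0)                      # (6/20)/(10/100)
  expect_equal(fe$p, oracle_hyper_upper(6, 10, 20, 100))

  # null expectation: k = n*K/N gives fold 1
  gene_set0 <- c(universe[1:2], universe[11:28])  # k = 2, n = 20
  expect_equal(fold_enrichment(gene_set0, category, universe)$fold, 1.0)

  # EASE variant is more conservative
  expect_gt(fold_enrichment(gene_set, category, universe, ease = TRUE)$p,
            fe$p)
  expect_error(fold_enrichment(character(0), category, universe), "degenerate")
})

test_that("BH adjustment is monotone and bounded across categories", {
  set.seed(4)
  universe <- sprintf("g%03d", 1:200)
  cats <- tibble::tibble(
    gene_id = sample(universe, 300, replace = TRUE),
    category = sample(paste0("c", 1:12), 300, replace = TRUE)
  ) |> dplyr::distinct()
  fe <- fold_enrichment(sample(universe, 40), cats, universe)
  expect_true(all(fe$p_adj >= fe$p))
  expect_true(all(fe$p_adj <= 1))
  ord <- order(fe$p)
  expect_true(all(diff(fe$p_adj[ord]) >= -1e-12))
  expect_equal(fe$p_adj, p.adjust(fe$p, "BH"))
})

test_that("TSS profiles bin region midpoints strand-aware around 5' ends", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          tss = 50000L)
  map <- tibble::tibble(chrom = "chr1", start = 49950L, end = 50050L)
  pr <- tss_distance_profile(map, genes, window = 10000L, bin = 1000L)
  expect_equal(sum(pr$count), 1L)
  expect_equal(pr$count[pr$bin_start == 0], 1L)  # midpoint exactly at the TSS

  # minus-strand gene: a region downstream in genome coords is upstream
  genes_m <- dplyr::mutate(genes, strand = "-")
  map2 <- tibble::tibble(chrom = "chr1", start = 52400L, end = 52600L)
  pr2 <- tss_distance_profile(map2, genes_m, window = 10000L, bin = 1000L)
  expect_equal(pr2$count[pr2$bin_start == -3000], 1L)
  expect_error(tss_distance_profile(map, genes, window = 500L, bin = 300L),
               "multiple")
})

test_that("uniform regions give a flat TSS profile, planted promoters a central peak", {
  set.seed(60)
  genome <- tibble::tibble(chrom = "chr1", size = 1e7)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                          strand = "+",
                          tss = as.integer(seq(3e5, 9.7e6, length.out = 20)))
  start <- as.integer(sample(0:(1e7 - 200), 10000))
  uniform <- tibble::tibble(chrom = "chr1", start = start, end = start + 200L)
  pr <- tss_distance_profile(uniform, genes, window = 50000L, bin = 1000L)
  expect_lt(max(pr$count), 3 * mean(pr$count))

  cfg <- small_sim_config(seed = 23)
  gg <- sim_genome(cfg)
  truth <- sim_plant_elements(gg$genome, gg$genes, cfg)
  prox <- truth$elements[truth$elements$intended_klass == "proximal", ]
  pp <- tss_distance_profile(prox, gg$genes, window = 50000L, bin = 1000L)
  peak_bin <- pp$bin_start[which.max(pp$count)]
  expect_lte(abs(peak_bin), 2000)
})
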