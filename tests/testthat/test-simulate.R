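# Synthetic-data generator: determinism, planted structure, library format,
# expression model.

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(background_fraction = 1.2), "fractions")
  expect_error(sim_config(n_elements = 50, n_genes = 300, d2_fraction = 0.2),
               "budget")
  cfg <- sim_config(seed = 1, n_genes = 5000, chrom_length = 1e6,
                    d2_fraction = 0, proximal_fraction = 0)
  expect_error(sim_genome(cfg), "density")
})

test_that("the dataset is a pure function of the configuration", {
  cfg <- small_sim_config(seed = 99, n_fragments = 300)
  d1 <- simulate_dataset(cfg, withr::local_tempdir())
  d2 <- simulate_dataset(cfg, withr::local_tempdir())
  expect_identical(readLines(d1$paths$genes), readLines(d2$paths$genes))
  expect_identical(readLines(d1$paths$sam[1]), readLines(d2$paths$sam[1]))
  expect_identical(readLines(d1$paths$track), readLines(d2$paths$track))
  expect_equal(d1$expression, d2$expression)
  # the two libraries of one dataset differ
  expect_false(identical(readLines(d1$paths$sam[1]),
                         readLines(d1$paths$sam[2])))
})

test_that("genes are placed on every chromosome with non-overlapping basal windows", {
  cfg <- small_sim_config(seed = 42)
  gg <- sim_genome(cfg)
  expect_equal(nrow(gg$genes), cfg$n_genes)
  expect_setequal(unique(gg$genes$chrom), gg$genome$chrom)
  by_chrom <- split(gg$genes$tss, gg$genes$chrom)
  expect_true(all(vapply(by_chrom, function(t) min(diff(sort(t))) > 4000,
                         logical(1))))
})

test_that("planted elements realize the intended P/D1/D2 structure", {
  cfg <- small_sim_config(seed = 7)
  gg <- sim_genome(cfg)
  truth <- sim_plant_elements(gg$genome, gg$genes, cfg)
  expect_equal(nrow(truth$elements), cfg$n_elements)
  n_d2 <- round(cfg$d2_fraction * cfg$n_genes)
  gt <- truth$gene_truth
  expect_equal(sum(gt$intended_group == "D2"), n_d2)
  expect_true(all(gt$intended_n_distal[gt$intended_group != "D2"] <= 2))
  # intended-proximal elements have midpoints within 2 kb of their gene's TSS
  prox <- truth$elements[truth$elements$intended_klass == "proximal", ]
  tss <- gg$genes$tss[match(prox$target_gene, gg$genes$gene_id)]
  expect_true(all(abs((prox$start + prox$end) %/% 2 - tss) <= 2000))
  # intended-distal midpoints lie 2-500 kb from their gene's TSS
  dist <- truth$elements[truth$elements$intended_klass == "distal", ]
  tss_d <- gg$genes$tss[match(dist$target_gene, gg$genes$gene_id)]
  dd <- abs((dist$start + dist$end) %/% 2 - tss_d)
  expect_true(all(dd > 2000 & dd <= 500000))
})

test_that("every element sits in a scored peak and decoys sit in none", {
  cfg <- small_sim_config(seed = 13)
  gg <- sim_genome(cfg)
  truth <- sim_plant_elements(gg$genome, gg$genes, cfg)
  flagged <- intersect_any(truth$elements, truth$track)
  expect_true(all(flagged$overlaps))
  peaks <- intersect_any(truth$track, truth$elements)
  frac_decoy <- mean(!peaks$overlaps)
  n_decoy <- round(cfg$decoy_fraction / (1 - cfg$decoy_fraction) *
                     cfg$n_elements)
  expect_equal(sum(!peaks$overlaps), n_decoy)
  expect_equal(frac_decoy, n_decoy / nrow(truth$track))
})

test_that("libraries emit consistent proper pairs with TLEN equal to the span", {
  cfg <- small_sim_config(seed = 3, n_fragments = 400)
  gg <- sim_genome(cfg)
  truth <- sim_plant_elements(gg$genome, gg$genes, cfg)
  sam <- sim_library(truth, gg$genome, cfg, library_index = 1)
  frag <- attr(sam, "fragments")
  expect_equal(nrow(frag), 400L)
  body <- sam[!startsWith(sam, "@")]
  expect_equal(length(body), 800L)          # two records per fragment
  f <- read_sam(textConnection_path(sam))
  expect_equal(dplyr::n_distinct(f$qname), 400L)
  expect_true(all(f$flag %in% c(99L, 147L, 83L, 163L)))
  expect_true(all(f$mapq == 42L))
  left <- f[f$tlen > 0, ]
  expect_equal(left$tlen,
               frag$end[match(left$qname, frag$qname)] -
                 frag$start[match(left$qname, frag$qname)])
})

test_that("corrupted pairs are emitted at the configured rate and removed by the filter", {
  cfg <- small_sim_config(seed = 29, n_fragments = 2000,
                          corrupt_fraction = 0.05)
  gg <- sim_genome(cfg)
  truth <- sim_plant_elements(gg$genome, gg$genes, cfg)
  sam <- sim_library(truth, gg$genome, cfg, library_index = 1)
  f <- read_sam(textConnection_path(sam))
  fr <- fragments_from_pairs(assign_strand(filter_alignments(f)), "L1")
  lost <- 1 - nrow(fr) / 2000
  # binomial expectation: about 2/3 of corrupted pairs lose the whole
  # fragment (secondary flag or low MAPQ); orphaned pairs keep one record
  # that the pairing step then drops as an orphan, losing the fragment too
  expect_gt(lost, 0.02)
  expect_lt(lost, 0.10)
  st <- fragment_stats(fr)
  expect_gt(st$n_orphans, 0L)
})

test_that("expression boosts intended-D2 genes and categories track the truth", {
  cfg <- small_sim_config(seed = 37)
  gg <- sim_genome(cfg)
  truth <- sim_plant_elements(gg$genome, gg$genes, cfg)
  expr <- sim_expression(truth, gg$genes, cfg)
  expect_true(all(expr$expression$fpkm >= 0))
  gt <- truth$gene_truth
  d2 <- expr$expression$fpkm[gt$intended_group == "D2"]
  d1 <- expr$expression$fpkm[gt$intended_group == "D1"]
  expect_gt(median(d2), median(d1))

  # multiplier 1: the groups are exchangeable draws from one distribution
  cfg0 <- small_sim_config(seed = 37, d2_effect = 1)
  expr0 <- sim_expression(truth, gg$genes, cfg0)
  r <- rank_sum_test(expr0$expression$fpkm[gt$intended_group == "D2"],
                     expr0$expression$fpkm[gt$intended_group == "D1"])
  expect_gt(r$p_two_sided, 0.001)

  cats <- expr$categories
  frac_cancer <- function(g) mean(g %in% cats$gene_id[cats$category == "cancer_like"])
  expect_gt(frac_cancer(gt$gene_id[gt$intended_group == "D2"]),
            frac_cancer(gt$gene_id[gt$intended_group == "none"]))
})
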