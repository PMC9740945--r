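# regmapr

Downstream analysis of ChIP-enriched lentiviral massively parallel reporter
assay (ChIP-lentiMPRA) experiments, in which a genome-wide library of
candidate regulatory elements — pre-enriched by H3K27ac chromatin
immunoprecipitation and selected for reporter activity in the assay — is
sequenced as paired-end fragments and mapped back to the genome. The package
takes the pipeline from alignment records to biology:

1. **Fragment recovery** — properly-paired primary alignments with
   MAPQ ≥ 10 are kept, the originating DNA chain is read off the SAM flag
   combinations (99/147 = plus, 83/163 = minus), and each read pair is
   collapsed to the outer span of its mates (the cloned fragment).
2. **Region calling** — fragments of the same orientation are merged
   (book-ended included), each merged region is quantified as
   RPM = fragments × 10⁶ / library total, orientations are combined, and
   only regions with RPM > 10 (strictly) are retained; the per-library maps
   are then unioned, strand-blind, into the unique map of *mapped regions*.
3. **Feature enrichment** — the fraction of mapped regions overlapping a
   feature track (H3K27ac peaks, DHS or TFBS clusters, CAGE peaks,
   super-enhancers) is compared with random region sets matched in count,
   length multiset and per-chromosome distribution, with an add-one
   permutation p-value `(1 + #{null ≥ obs}) / (1 + n)`.
4. **Gene association** — GREAT-style basal+extension regulatory domains
   (basal ±2 kb around the TSS, extended to the nearest neighbouring basal
   domain, at most 500 kb); a region associates with every gene whose
   extended domain contains its midpoint. Regions within ±2 kb of a 5′ end
   are *proximal* (P), those 2–500 kb away *distal* (D); genes split into
   P (≥ 1 proximal region), D1 (1–2 distal regions) and D2 (≥ 3 distal
   regions).
5. **Group statistics** — two-sided Mann–Whitney rank-sum comparisons of
   FPKM expression between gene groups (0.5 FPKM cutoff), category
   composition percentages, and hypergeometric fold enrichment
   `(k/n)/(K/N)` with Benjamini–Hochberg correction.

A deterministic synthetic-data generator (`sim_config()`,
`simulate_dataset()`) plants regulatory elements with a known P/D1/D2
structure, emits paired-end SAM libraries, a scored H3K27ac-like peak track
and an expression table, so the whole pipeline can be exercised and
validated end to end without any external data.

Everything is tidyverse-shaped: functions take data frames first and return
tibbles, fitted results have `tidy()`/`glance()` methods and `autoplot()`
views.

## Worked example

```r
library(regmapr)

cfg <- sim_config(seed = 11, n_chroms = 2, chrom_length = 3e6, n_genes = 40,
                  n_elements = 30, n_fragments = 20000,
                  background_fraction = 0, proximal_fraction = 0.3)
sim <- simulate_dataset(cfg, file.path(tempdir(), "demo"))

res <- region_map_from_sam(sim$paths$sam)   # SAM -> fragments -> region map
res$map
#> # A tibble: 30 × 7
#>   region_id    chrom  start    end strand libraries n_libraries
#>   <chr>        <chr>  <int>  <int> <chr>  <chr>           <int>
#> 1 region_00001 chr1  202293 203695 *      L1,L2               2
#> 2 region_00002 chr1  219211 220594 *      L1,L2               2
#> 3 region_00003 chr1  284464 285923 *      L1,L2               2
#> # i 27 more rows

recovery_metrics(res$map, sim$truth$elements)
#>   n_regions n_elements recall precision
#> 1        30         30      1         1
```

All 30 planted elements are recovered as exactly 30 regions (recall and
precision 1 on this clean two-library simulation). Associating the map with
genes and partitioning:

```r
genes  <- read_gene_annotation(sim$paths$genes)
genome <- read_genome(sim$paths$genome)
groups <- build_domains(genes, genome) |>
  associate_regions(map = res$map) |>
  partition_genes()
dplyr::count(groups, group)
#>   group      n
#> 1 D1        19
#> 2 D2         4
#> 3 P_only     3
```

The four D2 genes are exactly the genes the generator loaded with three
distal elements. Enrichment of the map in the planted peak track, against
100 matched random sets, and the D2-vs-D1 expression comparison:

```r
enrichment_test(res$map, read_bed(sim$paths$track), genome,
                n_replicates = 100, seed = 17, track_name = "H3K27ac")
#> Enrichment of 30 regions in 'H3K27ac'
#>   observed: 100.0%  null mean: 1.7% (100 matched random sets)
#>   ratio: 58.82  empirical p: 0.009901

expr <- read_expression(sim$paths$expression)
rank_sum_test(expr$fpkm[expr$gene_id %in% groups$gene_id[groups$D2]],
              expr$fpkm[expr$gene_id %in% groups$gene_id[groups$D1]])
#> Mann-Whitney rank-sum (normal_approx): U = 68, n = 4/17, two-sided p = 0.002697
```

Every region overlaps a peak while matched random regions do so 1.7% of the
time (ratio ≈ 59, the smallest p an add-one estimator can give at 100
replicates), and the distal-element-rich D2 genes are expressed
significantly higher than D1 genes — the qualitative pattern the assay is
designed to reveal.

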