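# Basal+extension regulatory domains, association, and the P/D1/D2 partition.

gene_tbl <- function(tss, strand = "+", chrom = "chr1",
                     id = sprintf("g%02d", seq_along(tss))) {
  tibble::tibble(gene_id = id, chrom = chrom, strand = strand,
                 tss = as.integer(tss))
}

test_that("a lone gene extends to max_ext on both sides", {
  genome <- tibble::tibble(chrom = "chr1", size = 2e6)
  d <- build_domains(gene_tbl(600000), genome)
  expect_equal(d$ext_start, 100000)
  expect_equal(d$ext_end, 1100000)
  expect_equal(c(d$basal_start, d$basal_end), c(598000, 602000))
})

test_that("extension stops at the neighbour's basal domain and gaps are shared", {
  genome <- tibble::tibble(chrom = "chr1", size = 2e6)
  d <- build_domains(gene_tbl(c(100000, 110000)), genome)
  a <- d[d$gene_id == "g01", ]
  b <- d[d$gene_id == "g02", ]
  expect_equal(a$ext_end, 108000)    # B's basal left edge
  expect_equal(b$ext_start, 102000)  # A's basal right edge
  # a midpoint between the basal domains lies in both extended domains
  mid <- 105000
  expect_true(a$ext_start <= mid && mid < a$ext_end)
  expect_true(b$ext_start <= mid && mid < b$ext_end)
})

test_that("domains clip at chromosome boundaries and reject impossible basal windows", {
  genome <- tibble::tibble(chrom = "chr1", size = 2e6)
  d <- build_domains(gene_tbl(1000), genome)
  expect_equal(d$ext_start, 0)
  expect_gte(d$basal_start, 0)
  expect_error(build_domains(gene_tbl(3e6), genome), "outside|beyond|absent")
})

test_that("domains satisfy their invariants and match the exhaustive oracle", {
  set.seed(31)
  genome <- tibble::tibble(chrom = c("chr1", "chr2"), size = c(3e6, 2e6))
  for (rep in 1:30) {
    n <- sample(2:12, 1)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:n),
      chrom = sample(genome$chrom, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      tss = as.integer(sample(seq(2500L, 1990000L, by = 13L), n))
    )
    d <- build_domains(genes, genome)
    o <- oracle_domains(genes, genome)
    o <- o[match(d$gene_id, o$gene_id), ]
    expect_equal(d$ext_start, as.numeric(o$ext_start))
    expect_equal(d$ext_end, as.numeric(o$ext_end))
    # basal inside extended; TSS inside extended
    expect_true(all(d$ext_start <= d$basal_start))
    expect_true(all(d$basal_end <= d$ext_end))
    expect_true(all(d$ext_start <= d$tss & d$tss < d$ext_end))
    # non-basal portions never intrude into another gene's basal domain
    for (i in seq_len(nrow(d))) {
      for (j in seq_len(nrow(d))) {
        if (i == j || d$chrom[i] != d$chrom[j]) next
        left_arm <- c(d$ext_start[i], d$basal_start[i])
        right_arm <- c(d$basal_end[i], d$ext_end[i])
        for (arm in list(left_arm, right_arm)) {
          ov <- min(arm[2], d$basal_end[j]) - max(arm[1], d$basal_start[j])
          expect_lte(ov, 0)
        }
      }
    }
  }
})

test_that("association classifies by midpoint distance and matches the per-pair oracle", {
  genome <- tibble::tibble(chrom = "chr1", size = 2e6)
  genes <- gene_tbl(c(500000, 800000))
  d <- build_domains(genes, genome)
  map <- tibble::tibble(
    region_id = c("r_prox", "r_dist"),
    chrom = "chr1",
    start = c(501000L, 549500L), end = c(502000L, 550500L)
  )
  a <- associate_regions(map, d)
  prox <- a[a$region_id == "r_prox" & a$gene_id == "g01", ]
  expect_equal(prox$klass, "proximal")     # midpoint 1500 bp downstream
  expect_equal(prox$signed_distance, 1500)
  dist <- a[a$region_id == "r_dist" & a$gene_id == "g01", ]
  expect_equal(dist$klass, "distal")       # midpoint 50 kb downstream
  expect_equal(dist$signed_distance, 50000)

  set.seed(77)
  for (rep in 1:30) {
    n_g <- sample(2:10, 1)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:n_g), chrom = "chr1",
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      tss = as.integer(sample(seq(10000, 1990000, by = 7), n_g))
    )
    dom <- build_domains(genes, genome)
    n_r <- sample(5:40, 1)
    start <- as.integer(sample(0:1990000, n_r))
    map <- tibble::tibble(region_id = sprintf("r%03d", 1:n_r), chrom = "chr1",
                          start = start,
                          end = start + sample(200:900, n_r, replace = TRUE))
    got <- associate_regions(map, dom)
    want <- oracle_associate(map, dom)
    expect_equal(nrow(got), nrow(want))
    expect_equal(paste(got$region_id, got$gene_id, got$signed_distance,
                       got$klass),
                 paste(want$region_id, want$gene_id, want$signed_distance,
                       want$klass))
  }
})

test_that("a midpoint exactly 2 kb from the TSS is proximal, beyond 500 kb excluded", {
  genome <- tibble::tibble(chrom = "chr1", size = 2e6)
  dom <- build_domains(gene_tbl(1000000), genome)
  map <- tibble::tibble(region_id = c("at2k", "beyond"),
                        chrom = "chr1",
                        start = c(1001950L, 1999000L),
                        end = c(1002050L, 1999100L))
  a <- associate_regions(map, dom)
  expect_equal(a$klass[a$region_id == "at2k"], "proximal")
  expect_false("beyond" %in% a$region_id)
})

test_that("association is monotone in the maximum extension", {
  set.seed(5)
  genome <- tibble::tibble(chrom = "chr1", size = 2e6)
  genes <- gene_tbl(sort(sample(50000:1950000, 8)))
  map <- random_intervals(40, chroms = "chr1", max_pos = 1900000,
                          max_len = 800)
  map$region_id <- sprintf("r%02d", seq_len(nrow(map)))
  keys <- lapply(c(5e4, 2e5, 5e5), function(me) {
    dom <- build_domains(genes, genome, max_ext = me)
    a <- associate_regions(map, dom, distal_max = me)
    paste(a$region_id, a$gene_id)
  })
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
})

test_that("gene partition realizes the P/D1/D2 rules", {
  assoc <- tibble::tibble(
    region_id = c("r1", "r2", "r3", "r4", "r1", "r5", "r6", "r7"),
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB", "gC", "gC"),
    signed_distance = c(1000, 30000, 40000, 50000, -1500, 10000, 5000, 9000),
    klass = c("proximal", "distal", "distal", "distal",
              "proximal", "distal", "distal", "distal")
  )
  pg <- partition_genes(assoc)
  gA <- pg[pg$gene_id == "gA", ]
  expect_true(gA$P && gA$D2 && !gA$D1)       # 3 distal + 1 proximal
  gB <- pg[pg$gene_id == "gB", ]
  expect_true(gB$P && gB$D1)                 # 1 distal
  gC <- pg[pg$gene_id == "gC", ]
  expect_true(!gC$P && gC$D1)                # 2 distal
  # D1 and D2 partition the distal genes
  expect_equal(sum(pg$D1 & pg$D2), 0L)
  expect_equal(sum(pg$D1) + sum(pg$D2), sum(pg$n_distal >= 1))
  # unassociated genes are absent
  expect_false("gZ" %in% pg$gene_id)

  rs <- summarize_regions(assoc)
  expect_equal(rs$n_genes[rs$region_id == "r1"], 2L)
  expect_true(rs$is_proximal[rs$region_id == "r1"])
})
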