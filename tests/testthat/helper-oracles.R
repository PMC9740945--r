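# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops, union-find, enumeration and direct
# summation.

# does interval i of `a` share >= 1 bp with any interval of `b`? (half-open)
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hit <- TRUE
        break
      }
    }
    hit
  }, logical(1))
}

# count of b-intervals overlapping each a-interval (optionally same strand)
oracle_overlap_count <- function(a, b, stranded = FALSE) {
  vapply(seq_len(nrow(a)), function(i) {
    n <- 0L
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      if (stranded && !is.null(a$strand) && !is.null(b$strand) &&
          a$strand[i] != "*" && b$strand[j] != "*" &&
          a$strand[i] != b$strand[j]) next
      if (a$start[i] < b$end[j] && b$start[j] < a$end[i]) n <- n + 1L
    }
    n
  }, integer(1))
}

# union-find merge of intervals (same chrom/strand handled by the caller);
# two intervals join when they overlap or their gap is <= max_gap
oracle_merge_group <- function(start, end, max_gap = 0L) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      gap <- max(start[i], start[j]) - min(end[i], end[j])
      if (gap <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    sel <- roots == r
    c(min(start[sel]), max(end[sel]))
  })
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

oracle_merge <- function(x, max_gap = 0L, stranded = TRUE) {
  keys <- if (stranded) split(x, paste(x$chrom, x$strand)) else split(x, x$chrom)
  out <- lapply(keys, function(part) {
    m <- oracle_merge_group(part$start, part$end, max_gap)
    data.frame(chrom = part$chrom[1], start = m[, 1], end = m[, 2],
               strand = if (stranded) part$strand[1] else "*")
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# SAM flag filter decided bit by bit from the binary decomposition
oracle_flag_keep <- function(flag, mapq, mapq_min = 10) {
  bits <- as.integer(intToBits(flag))[1:12]
  properly_paired <- bits[2] == 1
  unmapped <- bits[3] == 1
  secondary <- bits[9] == 1
  supplementary <- bits[12] == 1
  properly_paired && !unmapped && !secondary && !supplementary &&
    mapq >= mapq_min
}

oracle_flag_strand <- function(flag) {
  if (flag == 99 || flag == 147) return("+")
  if (flag == 83 || flag == 163) return("-")
  NA_character_
}

# exhaustive basal+extension domains: for each gene, scan every other gene
oracle_domains <- function(genes, genome, up = 2000, down = 2000,
                           max_ext = 500000) {
  sizes <- stats::setNames(genome$size, genome$chrom)
  n <- nrow(genes)
  out <- genes
  out$basal_start <- ifelse(genes$strand == "+",
                            genes$tss - up, genes$tss - down)
  out$basal_end <- ifelse(genes$strand == "+",
                          genes$tss + down, genes$tss + up)
  out$basal_start <- pmax(out$basal_start, 0)
  out$basal_end <- pmin(out$basal_end, sizes[genes$chrom])
  out$ext_start <- NA_real_
  out$ext_end <- NA_real_
  for (i in seq_len(n)) {
    left <- genes$tss[i] - max_ext
    right <- genes$tss[i] + max_ext
    for (j in seq_len(n)) {
      if (i == j || genes$chrom[j] != genes$chrom[i]) next
      # neighbouring basal boundaries between TSSs bound the extension
      if (genes$tss[j] < genes$tss[i]) left <- max(left, out$basal_end[j])
      if (genes$tss[j] > genes$tss[i]) right <- min(right, out$basal_start[j])
    }
    out$ext_start[i] <- min(max(left, 0), out$basal_start[i])
    out$ext_end[i] <- max(min(right, sizes[genes$chrom[i]]), out$basal_end[i])
  }
  out
}

# exhaustive association of every (region, gene) pair via the domain rule
oracle_associate <- function(map, domains, proximal_max = 2000,
                             distal_max = 500000) {
  rows <- list()
  for (i in seq_len(nrow(map))) {
    mid <- (map$start[i] + map$end[i]) %/% 2
    for (j in seq_len(nrow(domains))) {
      if (map$chrom[i] != domains$chrom[j]) next
      if (mid < domains$ext_start[j] || mid >= domains$ext_end[j]) next
      d <- if (domains$strand[j] == "+") mid - domains$tss[j]
           else domains$tss[j] - mid
      if (abs(d) > distal_max) next
      rows[[length(rows) + 1]] <- data.frame(
        region_id = map$region_id[i], gene_id = domains$gene_id[j],
        signed_distance = d,
        klass = if (abs(d) <= proximal_max) "proximal" else "distal")
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(region_id = character(), gene_id = character(),
                      signed_distance = numeric(), klass = character()))
  }
  out <- out[order(out$gene_id, out$signed_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact two-sided rank-sum p by enumerating every assignment of the pooled
# ranks to group A (no ties assumed)
oracle_ranksum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(outer(a, b, ">"))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">"))
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# upper-tail hypergeometric by direct summation of the pmf
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# random interval tibble for property tests
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_len = 60, stranded = FALSE) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE),
    strand = if (stranded) sample(c("+", "-"), n, replace = TRUE) else "*"
  )
}
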