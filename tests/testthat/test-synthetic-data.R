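test_that("simulate_genome hits target fractions and is deterministic", {
  g <- simulate_genome(100000, gene_fraction = 0.3, repeat_fraction = 0.5,
                       seed = 42)
  gene_bp <- sum(g$gene_intervals$end - g$gene_intervals$start)
  expect_lt(abs(gene_bp - 30000) / 30000, 0.05)
  rep_bp <- sum(g$repeat_intervals$end - g$repeat_intervals$start)
  expect_lt(abs(rep_bp - 50000) / 50000, 0.05)
  meth_bp <- sum(g$methylated_intervals$end - g$methylated_intervals$start)
  expect_equal(meth_bp, round(rep_bp * 0.97))
  expect_equal(hypomethylated_size(g), nchar(g$sequence) - meth_bp)

  g2 <- simulate_genome(100000, gene_fraction = 0.3, repeat_fraction = 0.5,
                        seed = 42)
  expect_identical(g, g2)
  expect_false(identical(
    g, simulate_genome(100000, 0.3, 0.5, seed = 43)))
})

test_that("simulate_genome zero-gene case and invariants", {
  g <- simulate_genome(5000, gene_fraction = 0, repeat_fraction = 0.4,
                       seed = 1)
  expect_equal(nrow(g$gene_intervals), 0L)
  # intervals within bounds, starts < ends, annotation sets non-overlapping
  for (f in c("gene_intervals", "repeat_intervals", "methylated_intervals")) {
    iv <- g[[f]]
    if (nrow(iv) == 0L) next
    expect_true(all(iv$start >= 0 & iv$end <= nchar(g$sequence)))
    expect_true(all(iv$start < iv$end))
    if (nrow(iv) > 1L) expect_true(all(iv$start[-1L] >= iv$end[-nrow(iv)]))
  }
})

test_that("simulate_genome rejects bad parameters", {
  expect_error(simulate_genome(500, 0.3, 0.3), "length")
  expect_error(simulate_genome(5000, 0.7, 0.5), "<= 1")
  expect_error(simulate_genome(5000, -0.1, 0.5), "fractions")
})

test_that("filtered library with leak_prob 0 never touches methylated space", {
  g <- simulate_genome(50000, 0.3, 0.5, seed = 7)
  lib <- simulate_library(g, "filtered", 500, leak_prob = 0, seed = 11)
  q <- data.frame(start = lib$reads$origin_start,
                  end = lib$reads$origin_end)
  ov <- methylfiltr:::overlaps_any(q, g$methylated_intervals)
  expect_identical(sum(ov), 0L)
  # read invariants: length bounds, sequence length = origin span
  len <- lib$reads$origin_end - lib$reads$origin_start
  expect_true(all(len >= 60 & len <= 140))
  expect_identical(nchar(lib$reads$sequence), as.integer(len))
})

test_that("library generation is reproducible and leak_prob admits reads", {
  g <- simulate_genome(50000, 0.3, 0.5, seed = 7)
  a <- simulate_library(g, "filtered", 300, leak_prob = 0.5, seed = 3)
  b <- simulate_library(g, "filtered", 300, leak_prob = 0.5, seed = 3)
  expect_identical(a, b)
  q <- data.frame(start = a$reads$origin_start, end = a$reads$origin_end)
  expect_gt(sum(methylfiltr:::overlaps_any(q, g$methylated_intervals)), 0L)
})

test_that("unfiltered reads are uniform and gene-hit rate matches truth", {
  g <- simulate_genome(200000, 0.3, 0.5, seed = 9)
  lib <- simulate_library(g, "unfiltered", 10000,
                          read_len_range = c(100, 100), seed = 13)
  # chi-square uniformity of start positions over 20 bins, alpha = 0.01
  glen <- nchar(g$sequence)
  bins <- cut(lib$reads$origin_start, breaks = seq(0, glen, length.out = 21),
              include.lowest = TRUE)
  p <- suppressWarnings(stats::chisq.test(table(bins))$p.value)
  expect_gt(p, 0.01)
  # binomial oracle: P(read overlaps a gene) = effective gene target / L.
  # Each gene interval's start window is its length + read_len - 1, clipped
  # at the chromosome end.
  iv <- g$gene_intervals
  target <- sum(pmin(iv$end, glen - 100 + 1) - pmax(iv$start - 100 + 1, 0))
  p_hit <- target / (glen - 100 + 1)
  q <- data.frame(start = lib$reads$origin_start, end = lib$reads$origin_end)
  obs <- mean(methylfiltr:::overlaps_any(q, iv))
  se <- sqrt(p_hit * (1 - p_hit) / 10000)
  expect_lt(abs(obs - p_hit), 3 * se)
})

test_that("inject_variants spectrum control and edge cases", {
  g <- simulate_genome(100000, 0.3, 0.3, seed = 21)
  expect_identical(nrow(inject_variants(g, 0)), 0L)

  v <- inject_variants(g, 2000, ti_weight = 1, tv_weight = 0, seed = 5)
  pair <- paste(pmin(v$ref, v$alt), pmax(v$ref, v$alt))
  expect_true(all(pair %in% c("A G", "C T")))
  expect_false(is.unsorted(v$position, strictly = TRUE))
  expect_true(all(v$ref != v$alt))

  # planted Ti/Tv of 7.5: multinomial sampling puts the realised ratio
  # within 3 s.e. of the target (s.e. from the binomial Ti proportion)
  v2 <- inject_variants(g, 5000, ti_weight = 7.5, tv_weight = 1, seed = 6)
  cls <- classify_substitution(v2$ref, v2$alt)
  ti <- sum(cls$substitution_class == "transition")
  p <- 7.5 / 8.5
  se_p <- sqrt(p * (1 - p) / 5000)
  expect_lt(abs(ti / 5000 - p), 3 * se_p)

  expect_error(inject_variants(g, nchar(g$sequence) + 1), "n_sites")
  expect_error(inject_variants(g, 10, ti_weight = 0, tv_weight = 0),
               "weights")
})

test_that("build_pileups plants both alleles and is error-free at rate 0", {
  g <- simulate_genome(20000, 0.3, 0.3, seed = 31)
  v <- inject_variants(g, 30, alt_fraction = 0.5, seed = 32)
  ps <- build_pileups(g, v, depth_mean = 12, error_rate = 0, seed = 33)
  # with no errors, every column's bases agree with consensus except at
  # variant columns, which carry only ref and alt
  violations <- 0L
  for (p in ps) {
    m <- methylfiltr:::pileup_count_matrix(p)
    clen <- nchar(p$consensus)
    cons <- strsplit(p$consensus, "")[[1L]]
    ctg <- as.integer(sub(".*ctg", "", p$contig_id))  # 1-based tile index
    for (pos in seq_len(clen)) {
      seen <- colnames(m)[m[pos, ] > 0]
      hit <- v[v$position == (ctg - 1L) * clen + pos - 1L, ]
      allowed <- if (nrow(hit) == 1L) c(hit$ref, hit$alt) else cons[pos]
      violations <- violations + sum(!seen %in% allowed)
    }
  }
  expect_identical(violations, 0L)
  # binomial oracle on allele counts: alt support at depth d ~ Bin(d, 0.5)
  snps <- call_snps(ps, max_depth = Inf)
  expect_gt(nrow(snps), 0L)
  frac <- sum(snps$support_b) / sum(snps$support_a + snps$support_b)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
})

test_that("generators honour derived RNG streams", {
  g <- simulate_genome(10000, 0.3, 0.3, seed = 50)
  lib <- simulate_library(g, "unfiltered", 10, seed = 50)
  v <- inject_variants(g, 10, seed = 50)
  # same top-level seed, different fixed offsets: outputs differ
  expect_false(identical(lib$reads$origin_start[1:10], v$position[1:10]))
  # and the caller's RNG state is untouched
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_genome(10000, 0.3, 0.3, seed = 50))
  expect_identical(before, .Random.seed)
})
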