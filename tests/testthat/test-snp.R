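make_pileup <- function(contig_id, consensus, reads) {
  structure(list(contig_id = contig_id, consensus = consensus,
                 reads = reads), class = "PileupAlignment")
}

test_that("support and depth rules on hand-built columns", {
  # 5 reads over a 4 bp contig; column 2 is A*3/G*2, column 3 is A*4/G*1
  reads <- data.frame(
    id = paste0("r", 1:5),
    start = 0L,
    sequence = c("AAAA", "AGAA", "AGAA", "AAGA", "TA-A"),
    stringsAsFactors = FALSE)
  p <- make_pileup("c1", "AAAA", reads)
  snps <- call_snps(list(p))
  expect_identical(nrow(snps), 1L)
  expect_identical(snps$position, 1L)  # 0-based
  expect_identical(snps$allele_a, "A")
  expect_identical(snps$allele_b, "G")
  expect_identical(snps$support_a, 3L)
  expect_identical(snps$support_b, 2L)
  expect_identical(snps$depth, 5L)
  expect_false(snps$multiallelic)

  # raising the required support kills the call
  expect_identical(nrow(call_snps(list(p), min_allele_support = 3)), 0L)
  expect_error(call_snps(list(p), min_allele_support = 0), "support")
  expect_identical(nrow(call_snps(list())), 0L)
})

test_that("gaps and N count toward depth but never allele support", {
  reads <- data.frame(
    id = paste0("r", 1:6), start = 0L,
    sequence = c("A", "A", "G", "G", "-", "N"), stringsAsFactors = FALSE)
  p <- make_pileup("c1", "A", reads)
  snps <- call_snps(list(p))
  expect_identical(snps$depth, 6L)
  expect_identical(snps$support_a + snps$support_b, 4L)
  # a column whose second "allele" is only gaps is not a SNP
  reads2 <- reads; reads2$sequence <- c("A", "A", "A", "-", "-", "-")
  expect_identical(nrow(call_snps(list(make_pileup("c1", "A", reads2)))), 0L)
})

test_that("high-coverage columns are excluded, absolutely or by auto rule", {
  deep <- data.frame(
    id = paste0("r", 1:32), start = 0L,
    sequence = rep(c("A", "G"), 16L), stringsAsFactors = FALSE)
  p <- make_pileup("c1", "A", deep)
  expect_identical(nrow(call_snps(list(p), max_depth = 30)), 0L)
  expect_identical(nrow(call_snps(list(p), max_depth = 32)), 1L)
  # auto mode: mean + 2 sd of the depth distribution
  shallow <- make_pileup("c2", strrep("A", 60),
                         data.frame(id = "s1", start = 0L,
                                    sequence = strrep("A", 60)))
  prof <- depth_profile(list(p, shallow), min_depth = 0, max_depth = Inf)
  auto_cut <- prof$mean + 2 * prof$sd
  got <- call_snps(list(p, shallow), max_depth = "auto")
  expect_identical(nrow(got), as.integer(32 <= auto_cut))
})

test_that("multiallelic columns are emitted once with the two best alleles", {
  reads <- data.frame(
    id = paste0("r", 1:9), start = 0L,
    sequence = c("A", "A", "A", "G", "G", "G", "T", "T", "C"),
    stringsAsFactors = FALSE)
  snps <- call_snps(list(make_pileup("c1", "A", reads)))
  expect_identical(nrow(snps), 1L)
  expect_true(snps$multiallelic)
  expect_identical(sort(c(snps$allele_a, snps$allele_b)), c("A", "G"))
})

test_that("call_snps matches an exhaustive per-column counter", {
  g <- simulate_genome(10000, 0.3, 0.3, seed = 61)
  ps <- build_pileups(g, inject_variants(g, 25, seed = 62), depth_mean = 9,
                      error_rate = 0.002, seed = 63)
  got <- call_snps(ps, max_depth = 30)
  want <- do.call(rbind, lapply(ps, function(p) {
    cols <- pileup_columns(p)
    hits <- lapply(seq_along(cols), function(i) {
      counts <- table(cols[[i]][cols[[i]] %in% c("A", "C", "G", "T")])
      counts <- counts[counts >= 2L]
      if (length(counts) >= 2L && length(cols[[i]]) <= 30L) {
        data.frame(contig_id = p$contig_id, position = i - 1L)
      }
    })
    do.call(rbind, hits)
  }))
  if (is.null(want)) want <- data.frame(contig_id = character(),
                                        position = integer())
  expect_identical(got[, c("contig_id", "position")],
                   want[order(want$contig_id, want$position), ,
                        drop = FALSE])
})

test_that("substitution classification is symmetric and complete", {
  expect_identical(classify_substitution("C", "T"),
                   data.frame(substitution_class = "transition",
                              pair_label = "C/T"))
  expect_identical(classify_substitution("T", "C"),
                   classify_substitution("C", "T"))
  expect_identical(classify_substitution("A", "T")$substitution_class,
                   "transversion")
  # all 6 unordered pairs map to the six labels, symmetrically
  pairs <- t(combn(c("A", "C", "G", "T"), 2))
  lab1 <- classify_substitution(pairs[, 1], pairs[, 2])$pair_label
  lab2 <- classify_substitution(pairs[, 2], pairs[, 1])$pair_label
  expect_identical(lab1, lab2)
  expect_identical(sort(lab1), sort(c("C/T", "G/A", "A/T", "C/G",
                                      "G/T", "A/C")))
  expect_error(classify_substitution("A", "A"), "distinct")
  expect_error(classify_substitution("A", "X"), "alleles")
})

test_that("Ti/Tv ratio and display truncation", {
  expect_equal(titv_ratio(EG_SNP_COUNTS), 24788 / 3454)
  expect_equal(titv_ratio(EG_SNP_COUNTS, display = TRUE), 7.17)
  expect_equal(titv_ratio(EO_SNP_COUNTS, display = TRUE), 7.52)
  expect_equal(titv_ratio(c("C/T" = 5, "A/T" = 5)), 1)
  expect_error(titv_ratio(c("C/T" = 5)), "transversions")
  # truncation, not rounding: 24788/3454 = 7.176... would round to 7.18
  expect_equal(round(24788 / 3454, 2), 7.18)
})

test_that("spectrum table conserves counts and matches records", {
  sp <- substitution_spectrum(EG_SNP_COUNTS)
  expect_equal(sp$count[sp$row == "transitions"], 24788)
  expect_equal(sp$count[sp$row == "transversions"], 3454)
  expect_equal(sp$count[sp$row == "total"], 28242)
  # conservation from records
  recs <- data.frame(pair_label = c("C/T", "C/T", "A/C"))
  sp2 <- substitution_spectrum(recs)
  expect_equal(sp2$count[sp2$row == "total"], nrow(recs))
  expect_equal(substitution_spectrum(recs[0, , drop = FALSE])$count,
               rep(0, 9))
})

test_that("snp_density divides by the eligible length", {
  prof <- structure(list(depths = c(rep(5, 200), rep(50, 40)),
                         mean = 12.5, sd = 18,
                         eligible_length = 200L, min_depth = 4L,
                         max_depth = 30L), class = "DepthProfile")
  expect_equal(snp_density(5, prof), 2.5)
  expect_equal(snp_density(0, prof), 0)
  bad <- prof; bad$eligible_length <- 0L
  expect_error(snp_density(5, bad), "undefined")
})

test_that("planted SNP density is recovered on clean pileups", {
  g <- simulate_genome(60000, 0.3, 0.3, seed = 71)
  v <- inject_variants(g, 120, alt_fraction = 0.5, seed = 72)
  ps <- build_pileups(g, v, depth_mean = 10, error_rate = 0, seed = 73)
  snps <- call_snps(ps)
  prof <- depth_profile(ps)
  d <- snp_density(snps, prof)
  # truth: planted sites per 100 bp of eligible sequence; the caller only
  # misses planted sites through allele-sampling or the depth window, both
  # of which also shrink the numerator, so agreement is loose (50%)
  d_true <- 100 * nrow(v) / prof$eligible_length
  expect_gt(d, 0.5 * d_true)
  expect_lte(d, 1.1 * d_true)
})
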