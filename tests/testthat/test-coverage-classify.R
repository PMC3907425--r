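rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("a full-length self-hit masks the whole target in one iteration", {
  set.seed(801)
  t1 <- rand_seq(300)
  rep <- iterative_subtract(c(q1 = t1), c(t1 = t1))
  expect_identical(rep$n_iterations, 1L)
  expect_equal(rep$per_target$masked_fraction, 1)
  expect_equal(rep$pct_gene_space_sampled, 100)
  expect_identical(rep$masked_targets[["t1"]], strrep("N", 300))
})

test_that("no passing hits means zero masking and zero iterations", {
  set.seed(802)
  rep <- iterative_subtract(c(q1 = rand_seq(80)), c(t1 = rand_seq(80)))
  expect_identical(rep$n_iterations, 0L)
  expect_equal(rep$total_masked_bp, 0L)
  expect_error(iterative_subtract(c(q = "ACGT"), character()), "targets")
})

test_that("tiling queries mask the brute-force interval union", {
  set.seed(803)
  tgt <- rand_seq(1000)
  # three ~200 bp queries with overlaps covering [100,700) of the target
  qs <- c(q1 = substr(tgt, 101, 350), q2 = substr(tgt, 301, 520),
          q3 = substr(tgt, 481, 700))
  rep <- iterative_subtract(qs, c(t1 = tgt))
  expect_lte(rep$n_iterations, 3L)
  expect_identical(rep$per_target$masked_bp, 600L)
  # the masked positions are exactly the union of the used hit intervals
  union_bp <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
    start = rep$hits_used$target_start + 1L,
    end = rep$hits_used$target_end))))
  expect_identical(rep$per_target$masked_bp, union_bp)
  # masked bp never decreases and the loop terminates
  expect_true(all(rep$hits_used$evalue <= 1e-20))
})

test_that("per-target mode masks each target's best hit per iteration", {
  set.seed(804)
  t1 <- rand_seq(300); t2 <- rand_seq(300)
  qs <- c(q1 = substr(t1, 1, 150), q2 = substr(t2, 1, 150))
  both <- iterative_subtract(qs, c(t1 = t1, t2 = t2), per_target = TRUE)
  expect_identical(both$n_iterations, 1L)
  expect_identical(both$per_target$masked_bp, c(150L, 150L))
})

test_that("EST tagging applies the inclusive threshold", {
  hits <- data.frame(query_id = c("e1", "e1", "e2", "e3"),
                     evalue = c(1e-21, 1e-5, 1e-19, 1e-20))
  tag <- est_tagged(hits, queries = c("e1", "e2", "e3", "e4"))
  expect_identical(tag$per_query$tagged, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tag$pct_tagged, 50)
})

test_that("gene-model QC keeps, rescues and drops per the rule", {
  recs <- data.frame(
    id = c("keep_lowaed", "drop_short", "rescued", "drop_norescue"),
    length = c(350, 250, 350, 350),
    aed = c(0.05, 0.05, 0.2, 0.2),
    best_evalue = c(NA, NA, 1e-25, NA))
  qc <- gene_model_qc(recs)
  expect_identical(qc$keep, c(TRUE, FALSE, TRUE, FALSE))
  expect_match(qc$reason[2], "length")
  expect_match(qc$reason[3], "hit")
  # boundary: AED exactly at the cutoff is not "low AED"
  expect_false(gene_model_qc(data.frame(id = "b", length = 350, aed = 0.1,
                                        best_evalue = NA))$keep)
  # rescue boundary is inclusive
  expect_true(gene_model_qc(data.frame(id = "b", length = 350, aed = 0.5,
                                       best_evalue = 1e-20))$keep)
  # monotone in the AED cutoff: lowering it never converts drop -> keep
  for (cut in c(0.3, 0.2, 0.1, 0.05)) {
    prev <- gene_model_qc(recs, aed_cutoff = cut)$keep
    lower <- gene_model_qc(recs, aed_cutoff = cut / 2)$keep
    expect_true(all(prev | !lower))
  }
  expect_error(gene_model_qc(data.frame(id = "x", length = 10, aed = 1.2)),
               "aed")
})

test_that("R-gene classes follow the domain-signature precedence", {
  expect_identical(classify_r_gene(c("kinase", "Pto")), 1L)
  expect_identical(classify_r_gene(c("CC", "NBS", "LRR")), 2L)
  expect_identical(classify_r_gene(c("TIR", "NBS", "LRR")), 3L)
  expect_identical(classify_r_gene(c("LRR", "TM")), 4L)
  expect_identical(classify_r_gene(c("LRR", "TM", "kinase")), 5L)
  expect_identical(classify_r_gene("NBS"), 6L)
  # precedence on supersets: TIR beats CC; kinase+LRR+TM beats Pto rule
  expect_identical(classify_r_gene(c("CC", "TIR", "NBS", "LRR")), 3L)
  expect_identical(classify_r_gene(c("kinase", "Pto", "LRR", "TM")), 5L)
  # total on the vocabulary power set, and deterministic
  vocab <- c("kinase", "Pto", "CC", "NBS", "LRR", "TIR", "TM")
  for (bits in 1:(2^7 - 1)) {
    d <- vocab[as.logical(bitwAnd(bits, 2^(0:6)))]
    cls <- classify_r_gene(d)
    expect_true(cls %in% 1:6)
    expect_identical(classify_r_gene(rev(d)), cls)
  }
  expect_error(classify_r_gene(character()), "empty")
  expect_error(classify_r_gene(c("NBS", "WD40")), "unknown")
})

test_that("miRNA match rules and the structure hook", {
  perfect <- list(query_start = 0L, query_end = 120L,
                  percent_identity = 96, score = NA)
  expect_identical(classify_mirna_match(perfect, 120L), "perfect")
  # full span but weak identity falls through to the partial rule
  weak <- list(query_start = 0L, query_end = 120L,
               percent_identity = 88, score = 120)
  expect_identical(classify_mirna_match(weak, 120L), "partial_candidate")
  expect_identical(classify_mirna_match(weak, 120L,
                                        structure_check = function(h) TRUE),
                   "partial")
  part <- list(query_start = 5L, query_end = 110L,
               percent_identity = 88, score = 120)
  expect_identical(classify_mirna_match(part, 120L), "partial_candidate")
  none <- list(query_start = 5L, query_end = 110L,
               percent_identity = 80, score = 200)
  expect_identical(classify_mirna_match(none, 120L), "none")
  low_score <- list(query_start = 5L, query_end = 110L,
                    percent_identity = 90, score = 80)
  expect_identical(classify_mirna_match(low_score, 120L), "none")
  # missing score with identity < 95 is a validation error
  bad <- list(query_start = 5L, query_end = 110L,
              percent_identity = 90, score = NA)
  expect_error(classify_mirna_match(bad, 120L), "score")
})
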