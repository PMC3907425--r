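# Gene-space coverage by in-silico subtractive hybridisation, plus the
# rule-based classifiers: EST tagging, gene-model QC, R-gene domain
# signatures and miRNA precursor matches.

#' Bundled deterministic local aligner
#'
#' A pluggable hit provider for [iterative_subtract()] backed by
#' [Biostrings::pairwiseAlignment()] with unit scores (match +1, mismatch
#' -1, each gap base -1; `N` matches nothing, so masked regions cannot
#' anchor hits). The reported `evalue` is the pseudo e-value
#' `m * n * 2^(-score)` -- deterministic and monotone in score but NOT
#' BLAST-compatible; production runs should supply external tabular hits.
#'
#' @param queries,targets named character vectors of sequences.
#' @param min_score hits scoring below this are not reported (default 10).
#' @return hit table (see [read_hits_tsv()] for columns), best hit per
#'   (query, target) pair.
#' @export
bundled_aligner <- function(queries, targets, min_score = 10) {
  lv <- c(DNA_BASES, "N")
  mat <- matrix(-1, 5L, 5L, dimnames = list(lv, lv))
  diag(mat) <- 1
  mat["N", "N"] <- -1
  hits <- list()
  for (qi in names(queries)) {
    for (ti in names(targets)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::BString(queries[[qi]]),
        Biostrings::BString(targets[[ti]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 1)
      sc <- Biostrings::score(aln)
      if (sc < min_score) next
      p <- aln@pattern@range
      s <- aln@subject@range
      npid <- Biostrings::nmatch(aln) /
        (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)) * 100
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = qi, target_id = ti,
        query_start = IRanges::start(p) - 1L,
        query_end = IRanges::end(p),
        target_start = IRanges::start(s) - 1L,
        target_end = IRanges::end(s),
        percent_identity = npid, score = sc,
        evalue = nchar(queries[[qi]]) * nchar(targets[[ti]]) * 2^(-sc),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(query_id = character(), target_id = character(),
                      query_start = integer(), query_end = integer(),
                      target_start = integer(), target_end = integer(),
                      percent_identity = numeric(), score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Gene-space coverage by iterative subtraction
#'
#' Repeatedly aligns queries against the (progressively masked) targets,
#' masks the single globally best passing hit's target interval with `N`,
#' and iterates until no hit passes the e-value cutoff. The masked fraction
#' of the target space quantifies how much of it the queries sample.
#' Queries are assumed repeat-masked upstream.
#'
#' The global best hit is the one with lowest e-value, ties broken by higher
#' score, then longer target interval, then lexicographic query id and
#' target id -- deterministic given a deterministic aligner. With
#' `per_target = TRUE` the best passing hit of every target is masked each
#' iteration instead (faster, coarser).
#'
#' @param queries,targets named character vectors (targets non-empty).
#' @param aligner hit provider `function(queries, targets) -> hit table`;
#'   defaults to [bundled_aligner()].
#' @param evalue_cutoff significance threshold (default 1e-20).
#' @param per_target mask the best hit per target each iteration.
#' @param max_iter safety bound on iterations.
#' @return a `CoverageReport` list: `per_target` (data.frame: `target_id`,
#'   `length`, `masked_bp`, `masked_fraction`), `total_target_bp`,
#'   `total_masked_bp`, `pct_gene_space_sampled`, `n_iterations`,
#'   `hits_used`, `masked_targets`.
#' @export
iterative_subtract <- function(queries, targets, aligner = bundled_aligner,
                               evalue_cutoff = 1e-20, per_target = FALSE,
                               max_iter = 10000L) {
  if (length(targets) == 0L) stop("no targets", call. = FALSE)
  if (is.null(names(targets)) || is.null(names(queries))) {
    stop("queries and targets must be named", call. = FALSE)
  }
  masked <- lapply(targets, function(t) logical(nchar(t)))
  cur <- targets
  used <- list()
  iter <- 0L
  repeat {
    if (iter >= max_iter) {
      warning("iterative_subtract: max_iter reached", call. = FALSE)
      break
    }
    hits <- tryCatch(aligner(queries, cur), error = function(e) {
      stop("aligner failed at iteration ", iter + 1L, ": ",
           conditionMessage(e), call. = FALSE)
    })
    validate_hits(hits)
    hits <- hits[!is.na(hits$evalue) & hits$evalue <= evalue_cutoff, ,
                 drop = FALSE]
    if (nrow(hits) == 0L) break
    iter <- iter + 1L
    ord <- order(hits$evalue, -hits$score,
                 -(hits$target_end - hits$target_start),
                 hits$query_id, hits$target_id)
    hits <- hits[ord, , drop = FALSE]
    take <- if (per_target) hits[!duplicated(hits$target_id), , drop = FALSE]
            else hits[1L, , drop = FALSE]
    for (j in seq_len(nrow(take))) {
      ti <- take$target_id[j]
      span <- (take$target_start[j] + 1L):take$target_end[j]
      masked[[ti]][span] <- TRUE
      seq <- strsplit(cur[[ti]], "")[[1L]]
      seq[span] <- "N"
      cur[[ti]] <- paste(seq, collapse = "")
      used[[length(used) + 1L]] <- take[j, , drop = FALSE]
    }
    mf_log("debug", "iterative_subtract: iteration %d masked %d hit(s)",
           iter, nrow(take))
  }
  per_tab <- data.frame(
    target_id = names(targets),
    length = nchar(targets),
    masked_bp = vapply(masked, sum, integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  per_tab$masked_fraction <- per_tab$masked_bp / per_tab$length
  total_bp <- sum(per_tab$length)
  total_masked <- sum(per_tab$masked_bp)
  hits_used <- if (length(used)) do.call(rbind, used) else NULL
  mf_log("info",
         "iterative_subtract: %d queries, %d targets, %d iterations, %d/%d bp masked",
         length(queries), length(targets), iter, total_masked, total_bp)
  structure(list(per_target = per_tab, total_target_bp = total_bp,
                 total_masked_bp = total_masked,
                 pct_gene_space_sampled = 100 * total_masked / total_bp,
                 n_iterations = iter, hits_used = hits_used,
                 masked_targets = cur),
            class = "CoverageReport")
}

#' @export
print.CoverageReport <- function(x, ...) {
  cat(sprintf(
    "CoverageReport: %d targets, %d iterations, %d/%d bp masked (%.1f%% of gene space sampled)\n",
    nrow(x$per_target), x$n_iterations, x$total_masked_bp,
    x$total_target_bp, x$pct_gene_space_sampled))
  invisible(x)
}

#' EST tagging at an e-value threshold
#'
#' A query is tagged iff its best (smallest) e-value is at or below the
#' cutoff ("not more than" reads inclusively).
#'
#' @param hits hit table with `query_id` and `evalue`.
#' @param queries character vector of all query ids (so queries with no
#'   hits count toward the denominator); defaults to the ids present in
#'   `hits`.
#' @param evalue_cutoff threshold (default 1e-20).
#' @return list with `per_query` (data.frame: `query_id`, `best_evalue`,
#'   `tagged`) and `pct_tagged`.
#' @export
est_tagged <- function(hits, queries = unique(hits$query_id),
                       evalue_cutoff = 1e-20) {
  best <- setNames(rep(NA_real_, length(queries)), queries)
  if (nrow(hits) > 0L) {
    got <- tapply(hits$evalue, hits$query_id, min)
    best[names(got)] <- got
  }
  tagged <- !is.na(best) & best <= evalue_cutoff
  list(per_query = data.frame(query_id = queries,
                              best_evalue = unname(best),
                              tagged = unname(tagged),
                              stringsAsFactors = FALSE),
       pct_tagged = if (length(queries)) 100 * sum(tagged) / length(queries)
                    else NA_real_)
}

#' Gene-model quality control
#'
#' Keep a model iff it is at least `min_len` bp and either its annotation
#' edit distance (AED) is below `aed_cutoff`, or it is rescued by a database
#' hit with e-value at or below `evalue_cutoff`.
#'
#' @param records data.frame with `id`, `length`, `aed` and `best_evalue`
#'   (the minimum e-value over reference databases; `NA` if no hit).
#' @param min_len length floor in bp (default 300).
#' @param aed_cutoff AED threshold (default 0.1; kept branch requires
#'   `aed < aed_cutoff`).
#' @param evalue_cutoff rescue threshold (default 1e-20, inclusive).
#' @return `records` with added `keep` (logical) and `reason` columns.
#' @export
#' @examples
#' gene_model_qc(data.frame(id = "g1", length = 350, aed = 0.05,
#'                          best_evalue = NA))$keep
gene_model_qc <- function(records, min_len = 300L, aed_cutoff = 0.1,
                          evalue_cutoff = 1e-20) {
  stopifnot(all(c("length", "aed") %in% names(records)))
  if (any(records$aed < 0 | records$aed > 1, na.rm = TRUE)) {
    stop("aed must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(records$best_evalue)) records$best_evalue <- NA_real_
  long_enough <- records$length >= min_len
  low_aed <- records$aed < aed_cutoff
  rescued <- !is.na(records$best_evalue) &
    records$best_evalue <= evalue_cutoff
  records$keep <- long_enough & (low_aed | rescued)
  records$reason <- ifelse(!long_enough, sprintf("length < %d", min_len),
                    ifelse(low_aed, sprintf("AED < %s", aed_cutoff),
                    ifelse(rescued,
                           sprintf("AED >= %s but hit <= %s", aed_cutoff,
                                   format(evalue_cutoff)),
                           "AED too high and no rescuing hit")))
  records
}

R_GENE_VOCAB <- c("kinase", "Pto", "CC", "NBS", "LRR", "TIR", "TM")

#' Classify a resistance-gene candidate by its domain signature
#'
#' Plant R genes fall into six classes by protein domain content:
#' class 1 = Pto-like kinases (kinase + Pto), class 2 = CC-NBS-LRR,
#' class 3 = TIR-NBS-LRR, class 4 = LRR-TM receptor-like proteins,
#' class 5 = LRR-TM-kinase receptor-like kinases, class 6 = uncategorized
#' (R-associated domains that fit none of the signatures). Precedence (most
#' specific signature first): 3, 2, 5, 4, 1.
#'
#' @param domains character vector of domain labels from
#'   `{kinase, Pto, CC, NBS, LRR, TIR, TM}`; must be non-empty (candidates
#'   without any R-associated domain are rejected upstream).
#' @return integer class 1-6.
#' @export
#' @examples
#' classify_r_gene(c("CC", "NBS", "LRR"))  # 2
classify_r_gene <- function(domains) {
  if (length(domains) == 0L) {
    stop("empty domain set: not an R-gene candidate", call. = FALSE)
  }
  bad <- setdiff(domains, R_GENE_VOCAB)
  if (length(bad) > 0L) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  has <- function(...) all(c(...) %in% domains)
  if (has("TIR", "NBS", "LRR")) return(3L)
  if (has("CC", "NBS", "LRR")) return(2L)
  if (has("LRR", "TM", "kinase")) return(5L)
  if (has("LRR", "TM")) return(4L)
  if (has("kinase", "Pto")) return(1L)
  6L
}

#' Classify a hit against a miRNA hairpin precursor
#'
#' A hit is a `perfect` match iff it spans the full hairpin and has identity
#' at or above `perfect_identity`; otherwise it is a `partial_candidate` iff
#' identity is at least `partial_identity` and score at least
#' `partial_score`. A candidate is promoted to `partial` only when an
#' external secondary-structure check (e.g. RNA folding of the hit region
#' vs the hairpin loop) confirms it; the default hook confirms nothing, so
#' candidates stay `partial_candidate` (unconfirmed).
#'
#' @param hit one hit record (list or one-row data.frame) with
#'   `query_start`, `query_end` (0-based half-open on the hairpin),
#'   `percent_identity` and `score` (`score` may be `NA` only when identity
#'   makes the perfect rule decidable, i.e. identity >= 95).
#' @param query_len hairpin precursor length in bp.
#' @param structure_check optional `function(hit) -> logical` hook.
#' @param perfect_identity,partial_identity,partial_score thresholds
#'   (defaults 95, 85, 100).
#' @return one of `"perfect"`, `"partial"`, `"partial_candidate"`, `"none"`.
#' @export
classify_mirna_match <- function(hit, query_len, structure_check = NULL,
                                 perfect_identity = 95,
                                 partial_identity = 85,
                                 partial_score = 100) {
  identity <- hit$percent_identity
  if (is.null(identity) || is.na(identity)) {
    stop("hit lacks percent_identity", call. = FALSE)
  }
  full_span <- !is.null(hit$query_start) && !is.null(hit$query_end) &&
    hit$query_start == 0L && hit$query_end == query_len
  if (full_span && identity >= perfect_identity) return("perfect")
  if (is.null(hit$score) || is.na(hit$score)) {
    stop("score required to evaluate a non-perfect match", call. = FALSE)
  }
  if (identity >= partial_identity && hit$score >= partial_score) {
    if (!is.null(structure_check) && isTRUE(structure_check(hit))) {
      return("partial")
    }
    return("partial_candidate")
  }
  "none"
}
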