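# SNP calling from multi-read contig pileups. A column yields a SNP iff at
# least two distinct nucleotide alleles are each supported by >= 2 separate
# reads and the column depth does not exceed the high-coverage cutoff
# (default 30; columns deeper than that sit in repetitive or duplicated
# regions and are excluded). Gaps and N never count as alleles or support
# but do count toward depth.

TRANSITION_PAIRS <- list(c("C", "T"), c("G", "A"))
PAIR_LABELS <- c("C/T", "G/A", "A/T", "C/G", "G/T", "A/C")

#' Classify a substitution as transition or transversion
#'
#' Transitions are `C/T` and `G/A`; the four transversions are `A/T`, `C/G`,
#' `G/T`, `A/C`. Symmetric in argument order; the returned `pair_label` is
#' order-normalized to those six spellings.
#'
#' @param allele_a,allele_b two distinct bases in `{A,C,G,T}` (vectorized).
#' @return data.frame with `substitution_class` and `pair_label`.
#' @export
#' @examples
#' classify_substitution("T", "C")  # transition, "C/T"
classify_substitution <- function(allele_a, allele_b) {
  a <- toupper(allele_a); b <- toupper(allele_b)
  if (length(a) != length(b)) stop("allele vectors differ in length",
                                   call. = FALSE)
  if (any(!a %in% DNA_BASES) || any(!b %in% DNA_BASES)) {
    stop("alleles must be in {A,C,G,T}", call. = FALSE)
  }
  if (any(a == b)) stop("alleles must be distinct", call. = FALSE)
  key <- paste(pmin(a, b), pmax(a, b))
  lab <- c("A C" = "A/C", "A G" = "G/A", "A T" = "A/T",
           "C G" = "C/G", "C T" = "C/T", "G T" = "G/T")[key]
  cls <- ifelse(lab %in% c("C/T", "G/A"), "transition", "transversion")
  data.frame(substitution_class = unname(cls), pair_label = unname(lab),
             stringsAsFactors = FALSE)
}

#' Call SNPs from pileup alignments
#'
#' @param pileups list of `PileupAlignment` (from [build_pileups()] or
#'   [read_ace()]).
#' @param min_allele_support minimum reads per allele (default 2).
#' @param max_depth maximum column depth; the default 30 matches the
#'   absolute high-coverage cutoff, `"auto"` uses mean + 2 sd of the depth
#'   distribution instead.
#' @return data.frame of SNP records: `contig_id`, `position` (0-based),
#'   `allele_a`, `allele_b` (the two best-supported alleles, ties broken
#'   alphabetically), `depth`, `support_a`, `support_b`,
#'   `substitution_class`, `pair_label`, `multiallelic` (3+ supported
#'   alleles, emitted once with the two best).
#' @export
call_snps <- function(pileups, min_allele_support = 2L, max_depth = 30) {
  if (min_allele_support < 1L) stop("min_allele_support must be >= 1",
                                    call. = FALSE)
  empty <- data.frame(contig_id = character(), position = integer(),
                      allele_a = character(), allele_b = character(),
                      depth = integer(), support_a = integer(),
                      support_b = integer(),
                      substitution_class = character(),
                      pair_label = character(), multiallelic = logical(),
                      stringsAsFactors = FALSE)
  if (length(pileups) == 0L) return(empty)
  if (identical(max_depth, "auto")) {
    dp <- depth_profile(pileups, min_depth = 0L, max_depth = Inf)
    max_depth <- dp$mean + 2 * dp$sd
    mf_log("info", "call_snps: auto max_depth = %.2f", max_depth)
  }
  out <- lapply(pileups, function(p) {
    m <- pileup_count_matrix(p)
    depth <- rowSums(m)
    allele <- m[, DNA_BASES, drop = FALSE]
    supported <- allele >= min_allele_support
    nsup <- rowSums(supported)
    hit <- which(nsup >= 2L & depth <= max_depth)
    if (length(hit) == 0L) return(NULL)
    # two best-supported alleles per hit column; ties alphabetical (columns
    # are in A,C,G,T order and max.col ties.method = "first")
    sup <- allele[hit, , drop = FALSE]
    sup[sup < min_allele_support] <- -1L
    a_idx <- max.col(sup, ties.method = "first")
    sup_a <- sup[cbind(seq_along(hit), a_idx)]
    sup[cbind(seq_along(hit), a_idx)] <- -1L
    b_idx <- max.col(sup, ties.method = "first")
    sup_b <- sup[cbind(seq_along(hit), b_idx)]
    data.frame(contig_id = p$contig_id, position = hit - 1L,
               allele_a = DNA_BASES[a_idx], allele_b = DNA_BASES[b_idx],
               depth = as.integer(depth[hit]),
               support_a = as.integer(sup_a),
               support_b = as.integer(sup_b),
               multiallelic = nsup[hit] > 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  cls <- classify_substitution(out$allele_a, out$allele_b)
  out$substitution_class <- cls$substitution_class
  out$pair_label <- cls$pair_label
  out <- out[order(out$contig_id, out$position),
             c("contig_id", "position", "allele_a", "allele_b", "depth",
               "support_a", "support_b", "substitution_class", "pair_label",
               "multiallelic")]
  row.names(out) <- NULL
  mf_log("info", "call_snps: %d pileups -> %d SNPs", length(pileups),
         nrow(out))
  out
}

#' Depth profile of a pileup set
#'
#' @param pileups list of `PileupAlignment`.
#' @param min_depth,max_depth closed depth interval defining
#'   `eligible_length`, the denominator of [snp_density()] (defaults 4-30).
#' @return a `DepthProfile` list: `depths` (integer vector over all contig
#'   positions), `mean`, `sd`, `eligible_length`, `min_depth`, `max_depth`.
#' @export
depth_profile <- function(pileups, min_depth = 4L, max_depth = 30L) {
  depths <- unlist(lapply(pileups, function(p) {
    rowSums(pileup_count_matrix(p))
  }), use.names = FALSE)
  if (is.null(depths)) depths <- numeric()
  structure(list(depths = depths, mean = mean(depths), sd = sd(depths),
                 eligible_length = sum(depths >= min_depth &
                                         depths <= max_depth),
                 min_depth = min_depth, max_depth = max_depth),
            class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf(
    "DepthProfile: %d positions, mean %.2f (sd %.2f), eligible [%s,%s] = %d bp\n",
    length(x$depths), x$mean, x$sd, format(x$min_depth), format(x$max_depth),
    x$eligible_length))
  invisible(x)
}

#' Transition/transversion ratio
#'
#' @param x SNP records from [call_snps()], or named counts per pair label
#'   (names among `C/T`, `G/A`, `A/T`, `C/G`, `G/T`, `A/C`).
#' @param display if `TRUE`, truncate (not round) to 2 decimal places, the
#'   convention used when quoting Ti/Tv in text.
#' @return the ratio transitions / transversions.
#' @export
#' @examples
#' titv_ratio(c("C/T" = 12391, "G/A" = 12397, "A/T" = 1928,
#'              "C/G" = 180, "G/T" = 696, "A/C" = 650), display = TRUE)
titv_ratio <- function(x, display = FALSE) {
  counts <- pair_counts(x)
  ti <- sum(counts[c("C/T", "G/A")])
  tv <- sum(counts[c("A/T", "C/G", "G/T", "A/C")])
  if (tv == 0) stop("no transversions: Ti/Tv undefined", call. = FALSE)
  r <- ti / tv
  if (display) truncate_decimal(r, 2L) else r
}

pair_counts <- function(x) {
  if (is.data.frame(x)) {
    counts <- table(factor(x$pair_label, levels = PAIR_LABELS))
    setNames(as.numeric(counts), PAIR_LABELS)
  } else {
    if (is.null(names(x)) || !all(names(x) %in% PAIR_LABELS)) {
      stop("counts must be named with the six pair labels", call. = FALSE)
    }
    full <- setNames(numeric(length(PAIR_LABELS)), PAIR_LABELS)
    full[names(x)] <- x
    full
  }
}

#' Substitution spectrum in marker-summary layout
#'
#' Six pair-label rows (transitions first), transition and transversion
#' subtotals, and the grand total.
#'
#' @inheritParams titv_ratio
#' @return data.frame with columns `row` and `count`; rows `C/T`, `G/A`,
#'   `A/T`, `C/G`, `G/T`, `A/C`, `transitions`, `transversions`, `total`.
#' @export
substitution_spectrum <- function(x) {
  counts <- pair_counts(x)
  ti <- sum(counts[c("C/T", "G/A")])
  tv <- sum(counts[c("A/T", "C/G", "G/T", "A/C")])
  data.frame(row = c(PAIR_LABELS, "transitions", "transversions", "total"),
             count = c(unname(counts), ti, tv, ti + tv),
             stringsAsFactors = FALSE)
}

#' SNP density per 100 bp
#'
#' Total SNPs divided by the length of regions whose coverage lies in the
#' closed depth interval of the profile (default 4-30), times 100.
#'
#' @param n_snps SNP count (or the records data.frame, whose rows are
#'   counted).
#' @param profile a `DepthProfile` from [depth_profile()].
#' @return SNPs per 100 bp.
#' @export
snp_density <- function(n_snps, profile) {
  if (is.data.frame(n_snps)) n_snps <- nrow(n_snps)
  stopifnot(inherits(profile, "DepthProfile"))
  if (profile$eligible_length == 0L) {
    stop("no positions with eligible coverage: density undefined",
         call. = FALSE)
  }
  100 * n_snps / profile$eligible_length
}
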