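# Island clustering of placed reads and assembly accounting. An "island" in
# the Lander-Waterman sense is a maximal set of reads connected by pairwise
# overlaps of at least `min_overlap` bp -- a contig (>= 2 reads) or a
# singleton. Overlap here is the size of the coordinate intersection of the
# reads' true placements; no sequence alignment is performed.

#' Cluster placed reads into overlap islands
#'
#' Single-linkage connected components where an edge joins two reads iff
#' their placements intersect by at least `min_overlap` bp. For two reads
#' with `start_i <= start_j` the intersection is
#' `min(end_i, end_j) - start_j`, so an edge exists iff
#' `start_j <= end_i - min_overlap` and read j is itself at least
#' `min_overlap` long. Components are therefore exactly the overlap
#' components of the shrunken intervals `[start, end - min_overlap]`
#' (touching counts), computed by a left-to-right sweep; reads shorter than
#' `min_overlap` can never join anything and are always singletons.
#'
#' @param reads a `ReadLibrary`, a list of them, or a data.frame with
#'   columns `start`, `end` (0-based half-open; an `id` column is optional).
#' @param min_overlap minimum pairwise overlap in bp to join (default 40).
#' @return data.frame with one row per read (sorted by start): `id`,
#'   `start`, `end`, and the assigned `island` index (islands numbered by
#'   leftmost member coordinate).
#' @export
#' @examples
#' reads <- data.frame(start = c(0, 60, 300), end = c(100, 160, 400))
#' cluster_islands(reads, min_overlap = 40)$island  # 1 1 2
cluster_islands <- function(reads, min_overlap = 40L) {
  if (!is.numeric(min_overlap) || min_overlap < 0) {
    stop("min_overlap must be >= 0", call. = FALSE)
  }
  reads <- as_placements(reads)
  n <- nrow(reads)
  if (n == 0L) {
    reads$island <- integer()
    return(reads)
  }
  ord <- order(reads$start, reads$end, reads$id)
  reads <- reads[ord, , drop = FALSE]
  island <- integer(n)
  joinable <- (reads$end - reads$start) >= min_overlap
  cur <- 0L
  max_shrunk_end <- -Inf
  for (i in seq_len(n)) {
    if (!joinable[i]) {
      island[i] <- NA_integer_  # singleton, numbered below
      next
    }
    if (reads$start[i] <= max_shrunk_end) {
      island[i] <- cur
    } else {
      cur <- cur + 1L
      island[i] <- cur
    }
    max_shrunk_end <- max(max_shrunk_end, reads$end[i] - min_overlap)
  }
  if (anyNA(island)) {
    island[is.na(island)] <- cur + seq_len(sum(is.na(island)))
  }
  # renumber islands by their leftmost member's coordinate
  first_start <- tapply(reads$start, island, min)
  rank <- rank(first_start, ties.method = "first")
  island <- as.integer(rank[as.character(island)])
  reads$island <- island
  row.names(reads) <- NULL
  reads
}

as_placements <- function(reads) {
  if (inherits(reads, "ReadLibrary")) reads <- list(reads)
  if (is.list(reads) && !is.data.frame(reads) &&
      all(vapply(reads, inherits, logical(1L), "ReadLibrary"))) {
    reads <- do.call(rbind, lapply(reads, function(lib) {
      data.frame(id = lib$reads$id, start = lib$reads$origin_start,
                 end = lib$reads$origin_end, stringsAsFactors = FALSE)
    }))
  }
  if (!is.data.frame(reads) || !all(c("start", "end") %in% names(reads))) {
    stop("reads must be a ReadLibrary or a data.frame with start/end",
         call. = FALSE)
  }
  if (is.null(reads$id)) {
    reads$id <- sprintf("read_%06d", seq_len(nrow(reads)))
  }
  reads[, c("id", "start", "end")]
}

#' Count islands in a read set
#'
#' @inheritParams cluster_islands
#' @param exclude_short if `TRUE`, singleton islands whose read is shorter
#'   than `singleton_min_len` are not counted (the assembly-table convention
#'   that drops <50 bp singletons); the default counts every island.
#' @param singleton_min_len length floor used when `exclude_short = TRUE`.
#' @return integer island count.
#' @export
count_islands <- function(reads, min_overlap = 40L, exclude_short = FALSE,
                          singleton_min_len = 50L) {
  cl <- cluster_islands(reads, min_overlap)
  if (nrow(cl) == 0L) return(0L)
  sizes <- tabulate(cl$island)
  if (!exclude_short) return(sum(sizes > 0L))
  span <- tapply(cl$end, cl$island, max) - tapply(cl$start, cl$island, min)
  sum(sizes > 1L) + sum(sizes == 1L & span >= singleton_min_len)
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together cover at
#' least half the total.
#'
#' @param lengths positive numeric vector.
#' @return the N50 length.
#' @export
#' @examples
#' n50(c(4, 3, 3, 2, 2, 2))  # 3
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("n50 of an empty set is undefined",
                                  call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Assembly summary in the style of a survey-sequencing statistics table
#'
#' Contigs are islands with >= 2 reads; singleton islands are split at
#' `singleton_min_len`. Unique sequences = contigs + singletons at or above
#' the floor. Contig length is the span of the union of its reads' placements.
#'
#' @param clustered output of [cluster_islands()].
#' @param singleton_min_len singleton length floor in bp (default 50).
#' @return an `AssemblySummary` list: `n_contigs`, `n_singletons_ge50`,
#'   `n_singletons_lt50`, `total_unique`, `total_unique_length`,
#'   `pct_unique_contigs`, `pct_reads_in_contigs`, `n50`, `max_length`,
#'   `mean_length`.
#' @export
summarize_assembly <- function(clustered, singleton_min_len = 50L) {
  stopifnot(is.data.frame(clustered), "island" %in% names(clustered))
  if (nrow(clustered) == 0L) {
    return(assembly_summary_from_counts(0L, 0L, 0L, total_unique_length = 0L))
  }
  span_start <- tapply(clustered$start, clustered$island, min)
  span_end <- tapply(clustered$end, clustered$island, max)
  sizes <- tapply(clustered$island, clustered$island, length)
  span <- as.integer(span_end - span_start)
  is_contig <- sizes >= 2L
  single_len <- span[!is_contig]
  uniq_len <- c(span[is_contig], single_len[single_len >= singleton_min_len])
  assembly_summary_from_counts(
    n_contigs = sum(is_contig),
    n_singletons_ge50 = sum(single_len >= singleton_min_len),
    n_singletons_lt50 = sum(single_len < singleton_min_len),
    pct_reads_in_contigs = round_half_away(
      100 * sum(sizes[is_contig]) / nrow(clustered)),
    total_unique_length = sum(uniq_len),
    n50 = if (length(uniq_len)) n50(uniq_len) else NA_integer_,
    max_length = if (length(uniq_len)) max(uniq_len) else NA_integer_,
    mean_length = if (length(uniq_len)) round_half_away(mean(uniq_len))
                  else NA_real_)
}

#' Assembly summary from pre-tabulated counts
#'
#' The accounting identities of an assembly table (total unique sequences,
#' percent unique that are contigs) applied to counts that may come from an
#' external assembler's report rather than from [cluster_islands()].
#'
#' @param n_contigs number of multi-read contigs.
#' @param n_singletons_ge50,n_singletons_lt50 singletons split at the length
#'   floor.
#' @param pct_reads_in_contigs optional, carried through.
#' @param total_unique_length,n50,max_length,mean_length optional, carried
#'   through.
#' @return an `AssemblySummary` list (see [summarize_assembly()]).
#' @export
#' @examples
#' s <- assembly_summary_from_counts(45370, 155442, 17405)
#' s$total_unique        # 200812
#' s$pct_unique_contigs  # 23
assembly_summary_from_counts <- function(n_contigs, n_singletons_ge50,
                                         n_singletons_lt50 = 0L,
                                         pct_reads_in_contigs = NA_real_,
                                         total_unique_length = NA_integer_,
                                         n50 = NA_integer_,
                                         max_length = NA_integer_,
                                         mean_length = NA_real_) {
  total_unique <- n_contigs + n_singletons_ge50
  structure(
    list(n_contigs = n_contigs,
         n_singletons_ge50 = n_singletons_ge50,
         n_singletons_lt50 = n_singletons_lt50,
         total_unique = total_unique,
         total_unique_length = total_unique_length,
         pct_unique_contigs = if (total_unique > 0)
           round_half_away(100 * n_contigs / total_unique) else NA_real_,
         pct_reads_in_contigs = pct_reads_in_contigs,
         n50 = n50, max_length = max_length, mean_length = mean_length),
    class = "AssemblySummary")
}

#' @export
print.AssemblySummary <- function(x, ...) {
  cat(sprintf(paste0(
    "AssemblySummary: %s contigs, %s singletons (>=50 bp), %s (<50 bp)\n",
    "  total unique %s | %% unique are contigs %s%% | N50 %s\n"),
    format(x$n_contigs, big.mark = ","),
    format(x$n_singletons_ge50, big.mark = ","),
    format(x$n_singletons_lt50, big.mark = ","),
    format(x$total_unique, big.mark = ","),
    format(x$pct_unique_contigs), format(x$n50)))
  invisible(x)
}

#' Island summary consumed by genome-size inference
#'
#' Bundles the quantities the mixed-assembly Lander-Waterman inversion needs:
#' library sizes, mean read length, the overlap threshold used for joining,
#' and the observed island count.
#'
#' @param n_filtered_reads,n_unfiltered_reads reads per library.
#' @param read_length mean read length L in bp.
#' @param overlap_threshold minimum detectable overlap T in bp.
#' @param n_contigs,n_singletons islands with >= 2 reads and with 1 read.
#' @return an `IslandSummary` list with `n_islands = n_contigs + n_singletons`.
#' @export
island_summary <- function(n_filtered_reads, n_unfiltered_reads, read_length,
                           overlap_threshold, n_contigs, n_singletons) {
  n_islands <- n_contigs + n_singletons
  if (n_islands > n_filtered_reads + n_unfiltered_reads) {
    stop("island count exceeds read count", call. = FALSE)
  }
  structure(list(n_filtered_reads = n_filtered_reads,
                 n_unfiltered_reads = n_unfiltered_reads,
                 read_length = read_length,
                 overlap_threshold = overlap_threshold,
                 n_islands = n_islands, n_contigs = n_contigs,
                 n_singletons = n_singletons),
            class = "IslandSummary")
}
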