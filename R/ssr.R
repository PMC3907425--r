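# Microsatellite (SSR) mining. A microsatellite is a tandem run of a 2-4 bp
# unit: at least 6 di-, 5 tri- or 4 tetranucleotide units, with one
# imperfection allowed per 10 repeat units. The run model is explicit:
#
#   run := perfect copy { gadget } perfect copy
#   gadget := perfect copy                      (0 imperfections)
#           | substituted copy (1 mismatch)     (1 imperfection)
#           | deleted copy (unit minus 1 base)  (1 imperfection)
#           | 1 inserted base, then a copy      (1 imperfection)
#
# A run of n units may carry at most floor(n/10) imperfections, must begin
# and end with a perfect unit copy, and at most one base may be inserted
# between consecutive copies. N never matches anything. Maximal runs are
# reported; within a unit length, runs contained in a longer run are
# suppressed. Mononucleotide runs are never reported, and sub-periodic
# motifs (e.g. ATAT as a tetramer) are handled at the shorter period.

#' Canonical motif class of a repeat unit
#'
#' The representative of a motif under cyclic rotation and reverse
#' complement: the lexicographically smallest string among all rotations of
#' the motif and all rotations of its reverse complement. `GA`, `AG`, `CT`,
#' `TC` all canonicalize to `AG`.
#'
#' @param motif repeat unit of length 2-4 over `{A,C,G,T}`; must not be a
#'   repetition of a shorter unit.
#' @return canonical class string.
#' @export
#' @examples
#' canonical_motif("GA")   # "AG"
#' canonical_motif("CGG")  # "CCG"
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  k <- nchar(motif)
  if (k < 2L || k > 4L || grepl("[^ACGT]", motif)) {
    stop("motif must be length 2-4 over {A,C,G,T}", call. = FALSE)
  }
  if (is_subperiodic(motif)) {
    stop("motif '", motif, "' is a repetition of a shorter unit",
         call. = FALSE)
  }
  min(c(rotations(motif), rotations(revcomp(motif))))
}

rotations <- function(x) {
  k <- nchar(x)
  vapply(seq_len(k), function(i) {
    paste0(substr(x, i, k), substr(x, 1L, i - 1L))
  }, character(1L))
}

is_subperiodic <- function(motif) {
  k <- nchar(motif)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L &&
        strrep(substr(motif, 1L, p), k %/% p) == motif) {
      return(TRUE)
    }
  }
  FALSE
}

#' Enumerate all canonical motif classes of a unit length
#'
#' Brute-force orbit enumeration: all `4^k` motifs, minus sub-periodic ones,
#' grouped under rotation and reverse-complement equivalence. Yields 4
#' dinucleotide, 10 trinucleotide and 33 tetranucleotide classes.
#'
#' @param unit_len 2, 3 or 4.
#' @return sorted character vector of canonical classes.
#' @export
#' @examples
#' enumerate_canonical_classes(2)  # AC AG AT CG
enumerate_canonical_classes <- function(unit_len) {
  if (!unit_len %in% 2:4) stop("unit_len must be 2, 3 or 4", call. = FALSE)
  motifs <- apply(do.call(expand.grid,
                          rep(list(DNA_BASES), unit_len)), 1L, paste,
                  collapse = "")
  motifs <- motifs[!vapply(motifs, is_subperiodic, logical(1L))]
  sort(unique(vapply(motifs, canonical_motif, character(1L),
                     USE.NAMES = FALSE)))
}

# all distinct strings obtained by deleting one base from the motif
deletion_variants <- function(motif) {
  k <- nchar(motif)
  unique(vapply(seq_len(k), function(i) {
    paste0(substr(motif, 1L, i - 1L), substr(motif, i + 1L, k))
  }, character(1L)))
}

#' Find microsatellites in sequences
#'
#' Scans each sequence for maximal runs of 2-4 bp units under the rules
#' described above. Overlapping calls of different unit lengths are both
#' reported; within a unit length, runs contained in a longer run are
#' suppressed. Output is sorted by (seq_id, start, unit_len).
#'
#' @param sequences named character vector of sequences over `{A,C,G,T,N}`
#'   (a single unnamed sequence is accepted).
#' @param min_units named map of minimum repeat units per unit length;
#'   default `c("2" = 6, "3" = 5, "4" = 4)`.
#' @return data.frame of SSR records: `seq_id`, `start`, `end` (0-based
#'   half-open), `motif` (as observed at the run start), `canonical_motif`,
#'   `unit_len`, `n_units`, `n_imperfections`, `sequence`.
#' @export
#' @examples
#' find_ssrs(c(x = "TTTACACACACACACGGG"))
find_ssrs <- function(sequences,
                      min_units = c("2" = 6L, "3" = 5L, "4" = 4L)) {
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  }
  if (any(grepl("[^ACGTN]", toupper(sequences)))) {
    stop("sequences must be over {A,C,G,T,N}", call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(sequences), function(id) {
    find_ssrs_one(id, toupper(sequences[[id]]), min_units)
  }))
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      canonical_motif = character(), unit_len = integer(),
                      n_units = integer(), n_imperfections = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  }
  row.names(out) <- NULL
  out
}

find_ssrs_one <- function(seq_id, s, min_units) {
  n <- nchar(s)
  chars <- strsplit(s, "")[[1L]]
  recs <- list()
  for (k in as.integer(names(min_units))) {
    minu <- as.integer(min_units[[as.character(k)]])
    if (n < k * minu) next
    runs <- list()
    tp <- tandem_profile(chars, n, k)
    for (i in candidate_starts(tp, n, k, minu)) {
      motif <- chars[i:(i + k - 1L)]
      motif_s <- paste(motif, collapse = "")
      if (any(motif == "N") || is_subperiodic(motif_s)) next
      best <- extend_run(chars, n, i, motif, k, minu, tp)
      if (!is.null(best)) {
        runs[[length(runs) + 1L]] <-
          data.frame(start = i - 1L, end = best[["end"]],
                     motif = motif_s, unit_len = k,
                     n_units = best[["units"]],
                     n_imperfections = best[["imps"]],
                     stringsAsFactors = FALSE)
      }
    }
    if (length(runs) == 0L) next
    runs <- do.call(rbind, runs)
    runs <- suppress_contained(runs)
    recs[[length(recs) + 1L]] <- runs
  }
  if (length(recs) == 0L) return(NULL)
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$start, recs$unit_len), , drop = FALSE]
  data.frame(seq_id = seq_id, start = recs$start, end = recs$end,
             motif = recs$motif,
             canonical_motif = vapply(recs$motif, canonical_motif,
                                      character(1L), USE.NAMES = FALSE),
             unit_len = recs$unit_len, n_units = recs$n_units,
             n_imperfections = recs$n_imperfections,
             sequence = substr(rep(s, nrow(recs)), recs$start + 1L,
                               recs$end),
             stringsAsFactors = FALSE)
}

# Drop runs (same unit length) whose interval lies inside another run's.
# Sorted by (start asc, end desc), a run is contained iff some earlier row
# already reaches at least as far right; ties on both coordinates dedupe.
suppress_contained <- function(runs) {
  ord <- order(runs$start, -runs$end)
  runs <- runs[ord, , drop = FALSE]
  keep <- logical(nrow(runs))
  maxend <- -1L
  for (j in seq_len(nrow(runs))) {
    if (runs$end[j] > maxend) {
      keep[j] <- TRUE
      maxend <- runs$end[j]
    }
  }
  runs[keep, , drop = FALSE]
}

# Shift-by-k self-match profile of a sequence, the substrate for all
# tandem-reachability pruning:
#   copies[p]  perfect tandem copies of the k-mer at p (p, p+k, ...)
#   sufmax[p]  largest tandem block (in copies) starting at or after p
#   esuf[p]    number of positions q >= p with chars[q] == chars[q+k]
tandem_profile <- function(chars, n, k) {
  eq <- chars[1:(n - k)] == chars[(1L + k):n]
  eq[is.na(eq)] <- FALSE
  r <- rle(eq)
  rl <- unlist(lapply(seq_along(r$lengths), function(j) {
    if (r$values[j]) rev(seq_len(r$lengths[j])) else rep(0L, r$lengths[j])
  }), use.names = FALSE)
  copies <- c(1L + rl %/% k, rep(1L, k))[1:n]
  list(copies = copies,
       sufmax = rev(cummax(rev(copies))),
       esuf = rev(cumsum(rev(c(as.integer(eq), rep(0L, k)))))[1:n],
       k = k)
}

# Sound pruning of run starts before the full frontier search. Any valid
# run either (a) uses no imperfection, so it opens with `minu` perfect unit
# copies at its start, or (b) has >= 10 units and m >= 1 imperfections, so
# its >= units - m perfect copies split into <= m + 1 blocks, the largest
# of which has >= ceiling(9m/(m+1)) >= 5 consecutive perfect copies -- i.e.
# the run contains a perfect 5-copy period-k tandem somewhere at or after
# its start. Random DNA almost never satisfies either.
candidate_starts <- function(tp, n, k, minu) {
  last <- n - k * minu + 1L
  if (last < 1L) return(integer())
  which(tp$copies[1:last] >= minu | tp$sufmax[1:last] >= 5L)
}

# Sound mid-search prune. A state at `pos` with u units and m imperfections
# has deficit d = 10m - u: it still needs fp >= d + 9e future perfect
# copies, where e is the number of future imperfections. Either e = 0 and
# the run finishes with d consecutive perfect copies of the motif starting
# exactly at pos, or e >= 1 and (i) the fp copies sit in <= e + 1 blocks,
# so the largest future tandem block has >= min(ceiling((d+9)/2), 9)
# copies, and (ii) every copy after a block's first consumes k self-matching
# positions, so d <= esuf/k + 1 - 8e <= esuf/k - 7.
state_viable <- function(d, pos, motif_here, tp) {
  if (d <= 0L) return(TRUE)
  if (pos > length(tp$copies)) return(FALSE)
  if (motif_here && tp$copies[pos] >= d) return(TRUE)   # finish perfectly
  if (d > tp$esuf[pos] %/% tp$k - 7L) return(FALSE)
  tp$sufmax[pos] >= min(as.integer(ceiling((d + 9L) / 2)), 9L)
}

# Longest valid run starting at 1-based position i whose first unit is the
# perfect copy `motif` (as a character vector). Memoized depth-first search
# over states (pos = next 1-based offset, units, imps, ins = insertion
# pending); records an endpoint whenever a perfect copy is laid down and
# the (min units, imperfection budget) constraints hold. Returns
# c(end = 0-based exclusive end, units, imps) or NULL.
extend_run <- function(chars, n, i, motif, k, minu, tp) {
  delv <- deletion_variants(paste(motif, collapse = ""))
  b_end <- -1L; b_units <- 0L; b_imps <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  walk <- function(pos, units, imps, ins) {
    key <- as.character(((pos * 4096 + units) * 512 + imps) * 2 + ins)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    here_end <- pos + k - 1L
    motif_here <- here_end <= n && all(chars[pos:here_end] == motif)
    if (!state_viable(10L * imps - units, pos, motif_here, tp)) {
      return(invisible())
    }
    if (here_end <= n) {
      if (motif_here) {                                    # perfect copy
        u2 <- units + 1L
        if (u2 >= minu && imps <= u2 %/% 10L &&
            (here_end > b_end ||
             (here_end == b_end &&
              (u2 > b_units || (u2 == b_units && imps < b_imps))))) {
          b_end <<- here_end; b_units <<- u2; b_imps <<- imps
        }
        walk(pos + k, u2, imps, 0L)
      } else {
        chunk <- chars[pos:here_end]
        if (!any(chunk == "N") && sum(chunk != motif) == 1L) {
          walk(pos + k, units + 1L, imps + 1L, 0L)         # substituted
        }
      }
    }
    if (pos + k - 2L <= n &&
        paste(chars[pos:(pos + k - 2L)], collapse = "") %in% delv) {
      walk(pos + k - 1L, units + 1L, imps + 1L, 0L)        # deleted
    }
    if (ins == 0L && pos <= n && chars[pos] != "N") {
      walk(pos + 1L, units, imps + 1L, 1L)                 # inserted base
    }
    invisible()
  }
  walk(i + k, 1L, 0L, 0L)
  if (b_end < 0L) NULL else c(end = b_end, units = b_units, imps = b_imps)
}

#' Frequency table of SSR calls
#'
#' Marginal counts per unit length plus per-canonical-class counts, with
#' each class's percentage computed over all SSRs of all unit lengths
#' combined, reported to 2 decimal places.
#'
#' @param records data.frame from [find_ssrs()].
#' @return list with `by_unit_len` (named counts for "2","3","4" and
#'   `total`) and `by_class` (data.frame: `canonical_motif`, `unit_len`,
#'   `count`, `pct`).
#' @export
ssr_frequency_table <- function(records) {
  by_unit <- vapply(c("2", "3", "4"), function(k) {
    sum(records$unit_len == as.integer(k))
  }, integer(1L))
  total <- nrow(records)
  if (total == 0L) {
    by_class <- data.frame(canonical_motif = character(),
                           unit_len = integer(), count = integer(),
                           pct = numeric(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(
      list(count = records$start),
      by = list(canonical_motif = records$canonical_motif,
                unit_len = records$unit_len),
      FUN = length)
    agg <- agg[order(agg$unit_len, -agg$count, agg$canonical_motif), ,
               drop = FALSE]
    agg$pct <- round(100 * agg$count / total, 2L)
    row.names(agg) <- NULL
    by_class <- agg[, c("canonical_motif", "unit_len", "count", "pct")]
  }
  list(by_unit_len = c(by_unit, total = total), by_class = by_class)
}

#' Total SSR count across datasets
#'
#' The accounting identity of a marker-summary table: per-dataset totals are
#' the sum of the di-, tri- and tetranucleotide counts, and the grand total
#' is the sum over datasets.
#'
#' @param counts matrix or data.frame with one row per dataset and columns
#'   di/tri/tetra.
#' @return list with `row_totals` and `grand_total`.
#' @export
#' @examples
#' ssr_totals(rbind(EG01 = c(14910, 5152, 3559), EO01 = c(6366, 2247, 1518)))
ssr_totals <- function(counts) {
  m <- as.matrix(counts)
  rt <- rowSums(m)
  list(row_totals = rt, grand_total = sum(rt))
}
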