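# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-derivations of the rules (brute force, exhaustive
# recursion), kept structurally different from the package implementations
# they check.

# --- single-linkage islands: all-pairs overlap + union-find ----------------

oracle_cluster_islands <- function(reads, min_overlap) {
  n <- nrow(reads)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n > 1L) {
    for (a in 1:(n - 1L)) {
      for (b in (a + 1L):n) {
        ov <- min(reads$end[a], reads$end[b]) -
          max(reads$start[a], reads$start[b])
        if (ov >= min_overlap) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

# --- SSR mining: exhaustive recursion over every parse from every start ----

oracle_subperiodic <- function(motif) {
  k <- length(motif)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L && all(motif == rep(motif[seq_len(p)], k %/% p))) {
      return(TRUE)
    }
  }
  FALSE
}

# The oracle shares one derived fact with the implementation (documented in
# the methods vignette): a partial parse with d = 10*imps - units > 0 can
# only be completed if it can end in d straight perfect copies of the motif
# from the current position, or a downstream perfect tandem block of at
# least min(ceiling((d+9)/2), 9) copies exists and d <= (self-matching
# positions ahead)/k - 7. Everything else (parse enumeration, maximality,
# suppression) is independent brute force.
oracle_tandem_profile <- function(ch, n, k) {
  eq <- c(ch[1:(n - k)] == ch[(1L + k):n], rep(FALSE, k))
  copies <- integer(n)
  run <- 0L
  for (p in n:1) {  # consecutive self-matches ahead of p
    run <- if (eq[p]) run + 1L else 0L
    copies[p] <- 1L + run %/% k
  }
  list(copies = copies, sufmax = rev(cummax(rev(copies))),
       esuf = rev(cumsum(rev(as.integer(eq)))))
}

oracle_ssrs_one_k <- function(ch, n, k, minu) {
  runs <- list()
  last <- n - k * minu + 1L
  if (last < 1L) return(NULL)
  tp <- oracle_tandem_profile(ch, n, k)
  for (i in seq_len(last)) {
    motif <- ch[i:(i + k - 1L)]
    if (any(motif == "N") || oracle_subperiodic(motif)) next
    motif_s <- paste(motif, collapse = "")
    delv <- unique(vapply(seq_len(k), function(j) {
      paste(motif[-j], collapse = "")
    }, character(1L)))
    best <- NULL
    rec <- function(pos, units, imps, ins) {
      d <- 10L * imps - units
      if (d > 0L) {
        if (pos > n) return()
        finishes_perfect <- pos + k - 1L <= n &&
          all(ch[pos:(pos + k - 1L)] == motif) && tp$copies[pos] >= d
        if (!finishes_perfect) {
          if (d > tp$esuf[pos] %/% k - 7L) return()
          if (tp$sufmax[pos] < min(ceiling((d + 9L) / 2), 9L)) return()
        }
      }
      if (pos + k - 1L <= n) {
        chunk <- ch[pos:(pos + k - 1L)]
        mism <- sum(chunk != motif)
        if (mism == 0L) {
          if (units + 1L >= minu && imps <= (units + 1L) %/% 10L) {
            cand <- c(end = pos + k - 1L, units = units + 1L, imps = imps)
            if (is.null(best) || cand[["end"]] > best[["end"]] ||
                (cand[["end"]] == best[["end"]] &&
                 cand[["units"]] > best[["units"]]) ||
                (cand[["end"]] == best[["end"]] &&
                 cand[["units"]] == best[["units"]] &&
                 cand[["imps"]] < best[["imps"]])) {
              best <<- cand
            }
          }
          rec(pos + k, units + 1L, imps, FALSE)
        } else if (mism == 1L && !any(chunk == "N")) {
          rec(pos + k, units + 1L, imps + 1L, FALSE)
        }
      }
      if (pos + k - 2L <= n &&
          paste(ch[pos:(pos + k - 2L)], collapse = "") %in% delv) {
        rec(pos + k - 1L, units + 1L, imps + 1L, FALSE)
      }
      if (!ins && pos <= n && ch[pos] != "N") {
        rec(pos + 1L, units, imps + 1L, TRUE)
      }
    }
    rec(i + k, 1L, 0L, FALSE)
    if (!is.null(best)) {
      runs[[length(runs) + 1L]] <- data.frame(
        start = i - 1L, end = best[["end"]], motif = motif_s, unit_len = k,
        n_units = best[["units"]], n_imperfections = best[["imps"]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(runs) == 0L) return(NULL)
  runs <- do.call(rbind, runs)
  # O(m^2) containment suppression within this unit length
  keep <- vapply(seq_len(nrow(runs)), function(a) {
    !any(runs$start <= runs$start[a] & runs$end >= runs$end[a] &
           (runs$start != runs$start[a] | runs$end != runs$end[a]))
  }, logical(1L))
  runs[keep, , drop = FALSE]
}

oracle_find_ssrs <- function(s, min_units = c("2" = 6L, "3" = 5L, "4" = 4L)) {
  ch <- strsplit(toupper(s), "")[[1L]]
  n <- length(ch)
  out <- do.call(rbind, lapply(as.integer(names(min_units)), function(k) {
    oracle_ssrs_one_k(ch, n, k, as.integer(min_units[[as.character(k)]]))
  }))
  if (is.null(out)) return(NULL)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# Bound-free naive recursion (only the trivial remaining-length prune).
# Feasible on short strings only; used to cross-check the shared
# reachability bound of implementation and oracle.
naive_find_ssrs <- function(s, min_units = c("2" = 6L, "3" = 5L, "4" = 4L)) {
  ch <- strsplit(toupper(s), "")[[1L]]
  n <- length(ch)
  out <- NULL
  for (k in as.integer(names(min_units))) {
    minu <- as.integer(min_units[[as.character(k)]])
    last <- n - k * minu + 1L
    if (last < 1L) next
    runs <- list()
    for (i in seq_len(last)) {
      motif <- ch[i:(i + k - 1L)]
      if (any(motif == "N") || oracle_subperiodic(motif)) next
      delv <- unique(vapply(seq_len(k), function(j) {
        paste(motif[-j], collapse = "")
      }, character(1L)))
      best <- NULL
      rec <- function(pos, units, imps, ins) {
        if (imps > (units + (n - pos + 1L) %/% (k - 1L)) %/% 10L) return()
        if (pos + k - 1L <= n) {
          chunk <- ch[pos:(pos + k - 1L)]
          mism <- sum(chunk != motif)
          if (mism == 0L) {
            if (units + 1L >= minu && imps <= (units + 1L) %/% 10L) {
              cand <- c(end = pos + k - 1L, units = units + 1L, imps = imps)
              if (is.null(best) || cand[["end"]] > best[["end"]] ||
                  (cand[["end"]] == best[["end"]] &&
                   cand[["units"]] > best[["units"]]) ||
                  (cand[["end"]] == best[["end"]] &&
                   cand[["units"]] == best[["units"]] &&
                   cand[["imps"]] < best[["imps"]])) {
                best <<- cand
              }
            }
            rec(pos + k, units + 1L, imps, FALSE)
          } else if (mism == 1L && !any(chunk == "N")) {
            rec(pos + k, units + 1L, imps + 1L, FALSE)
          }
        }
        if (pos + k - 2L <= n &&
            paste(ch[pos:(pos + k - 2L)], collapse = "") %in% delv) {
          rec(pos + k - 1L, units + 1L, imps + 1L, FALSE)
        }
        if (!ins && pos <= n && ch[pos] != "N") {
          rec(pos + 1L, units, imps + 1L, TRUE)
        }
      }
      rec(i + k, 1L, 0L, FALSE)
      if (!is.null(best)) {
        runs[[length(runs) + 1L]] <- data.frame(
          start = i - 1L, end = best[["end"]], motif = paste(motif, collapse = ""),
          unit_len = k, n_units = best[["units"]],
          n_imperfections = best[["imps"]], stringsAsFactors = FALSE)
      }
    }
    if (length(runs) == 0L) next
    runs <- do.call(rbind, runs)
    keep <- vapply(seq_len(nrow(runs)), function(a) {
      !any(runs$start <= runs$start[a] & runs$end >= runs$end[a] &
             (runs$start != runs$start[a] | runs$end != runs$end[a]))
    }, logical(1L))
    out <- rbind(out, runs[keep, , drop = FALSE])
  }
  if (is.null(out)) return(NULL)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# --- misc ------------------------------------------------------------------

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small tandem-bearing sequence: random backbone with planted repeat
# tracts (possibly mutated), to exercise the imperfection machinery
planted_repeat_seq <- function(n = 400L, n_tracts = 3L) {
  backbone <- strsplit(random_seq(n), "")[[1L]]
  for (t in seq_len(n_tracts)) {
    k <- sample(2:4, 1L)
    unit <- random_seq(k)
    copies <- sample(4:14, 1L)
    tract <- strsplit(strrep(unit, copies), "")[[1L]]
    if (runif(1L) < 0.5 && length(tract) > 2L) {  # one point mutation
      j <- sample(2:(length(tract) - 1L), 1L)
      tract[j] <- sample(c("A", "C", "G", "T"), 1L)
    }
    at <- sample(seq_len(n - length(tract)), 1L)
    backbone[at:(at + length(tract) - 1L)] <- tract
  }
  paste(backbone, collapse = "")
}

expect_same_ssr_calls <- function(s, info = NULL) {
  got <- find_ssrs(c(q = s))
  want <- oracle_find_ssrs(s)
  if (is.null(want)) {
    expect_identical(nrow(got), 0L, info = info)
  } else {
    cols <- c("start", "end", "motif", "unit_len", "n_units",
              "n_imperfections")
    expect_identical(got[, cols], want[, cols], info = info)
  }
}

# printed marker-table counts used across tests (inputs, not expectations)
EG_SNP_COUNTS <- c("C/T" = 12391, "G/A" = 12397, "A/T" = 1928,
                   "C/G" = 180, "G/T" = 696, "A/C" = 650)
EO_SNP_COUNTS <- c("C/T" = 5638, "G/A" = 5464, "A/T" = 866,
                   "C/G" = 97, "G/T" = 226, "A/C" = 287)
SSR_TABLE <- rbind(EG01 = c(14910, 5152, 3559), EO01 = c(6366, 2247, 1518))
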