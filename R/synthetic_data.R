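# Synthetic-data generators: a single-chromosome genome partitioned into
# gene, repeat and methylated-repeat intervals, read libraries drawn from it
# with or without methylation filtration, planted biallelic variants, and
# multi-read pileup alignments. All generators are deterministic given
# (seed, params) and record ground truth for recovery tests.

#' Simulate a genome with gene, repeat and methylated intervals
#'
#' Builds a single random chromosome partitioned into non-overlapping gene
#' intervals, repeat intervals and unannotated spacer. A subset of the repeat
#' intervals covering approximately `methylated_repeat_fraction` of the
#' repeat bp is marked methylated; the remainder of the genome is the
#' hypomethylated space that a methylation-filtered library can sample.
#'
#' Interval lengths are drawn around a mean of ~2 kb for genes and ~15 kb for
#' repeats: methylated repeat blocks in plant genomes are long heterochromatic
#' tracts, and long blocks also keep read-level filtration (see
#' [simulate_library()]) close to the idealised picture of filtration as a
#' pure genome-space restriction.
#'
#' @param length genome length in bp (>= 1000).
#' @param gene_fraction,repeat_fraction proportions of the genome covered by
#'   gene and repeat intervals; must sum to <= 1.
#' @param methylated_repeat_fraction proportion of repeat bp that is
#'   methylated (default 0.97).
#' @param seed integer seed; identical arguments give byte-identical genomes.
#' @param name identifier for the chromosome.
#' @param gene_mean_len,repeat_mean_len target mean interval lengths in bp.
#' @return a `GenomeModel`: list with `sequence` (character), `gene_intervals`,
#'   `repeat_intervals`, `methylated_intervals` (0-based half-open
#'   data.frames), and `name`.
#' @export
#' @examples
#' g <- simulate_genome(100000, 0.3, 0.5, seed = 42)
#' hypomethylated_size(g) / nchar(g$sequence)
simulate_genome <- function(length, gene_fraction, repeat_fraction,
                            methylated_repeat_fraction = 0.97,
                            seed = 1L, name = "chr1",
                            gene_mean_len = 2000L, repeat_mean_len = 15000L) {
  if (!is.numeric(length) || length < 1000) {
    stop("length must be >= 1000 bp", call. = FALSE)
  }
  fr <- c(gene_fraction, repeat_fraction, methylated_repeat_fraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr[1:2] > 1) ||
      methylated_repeat_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (gene_fraction + repeat_fraction > 1) {
    stop("gene_fraction + repeat_fraction must be <= 1", call. = FALSE)
  }
  length <- as.integer(length)

  with_seed(derive_seed(seed, 101L), {
    gene_bp <- round(length * gene_fraction)
    rep_bp <- round(length * repeat_fraction)
    other_bp <- length - gene_bp - rep_bp

    # split `total` bp into n parts with lengths ~ Dirichlet-ish around mean
    split_bp <- function(total, mean_len) {
      if (total <= 0) return(integer())
      n <- max(1L, round(total / mean_len))
      w <- runif(n, 0.5, 1.5)
      parts <- floor(total * w / sum(w))
      parts[1L] <- parts[1L] + (total - sum(parts))
      parts[parts > 0L]
    }

    seg_df <- function(type, lens) {
      data.frame(type = rep(type, length(lens)), len = lens)
    }
    segs <- rbind(
      seg_df("gene", split_bp(gene_bp, gene_mean_len)),
      seg_df("repeat", split_bp(rep_bp, repeat_mean_len)),
      seg_df("other", split_bp(other_bp, 3000L))
    )
    segs <- segs[sample.int(nrow(segs)), , drop = FALSE]
    ends <- cumsum(segs$len)
    starts <- ends - segs$len
    iv <- data.frame(start = as.integer(starts), end = as.integer(ends),
                     type = segs$type)

    gene_iv <- new_intervals(iv$start[iv$type == "gene"],
                             iv$end[iv$type == "gene"])
    rep_iv <- new_intervals(iv$start[iv$type == "repeat"],
                            iv$end[iv$type == "repeat"])
    gene_iv <- gene_iv[order(gene_iv$start), , drop = FALSE]
    rep_iv <- rep_iv[order(rep_iv$start), , drop = FALSE]
    row.names(gene_iv) <- NULL
    row.names(rep_iv) <- NULL

    # mark repeat intervals methylated until the target bp is reached
    meth_iv <- new_intervals()
    if (nrow(rep_iv) > 0L && methylated_repeat_fraction > 0) {
      target <- round(interval_total_bp(rep_iv) * methylated_repeat_fraction)
      ord <- sample.int(nrow(rep_iv))
      lens <- (rep_iv$end - rep_iv$start)[ord]
      take <- ord[cumsum(lens) <= target]
      deficit <- target - sum(rep_iv$end[take] - rep_iv$start[take])
      if (deficit > 0L) {
        # trim one further interval so methylated bp hits the target exactly
        nxt <- setdiff(ord, take)[1L]
        if (!is.na(nxt)) {
          meth_iv <- rbind(
            rep_iv[take, c("start", "end")],
            data.frame(start = rep_iv$start[nxt],
                       end = rep_iv$start[nxt] + as.integer(deficit))
          )
        } else meth_iv <- rep_iv[take, c("start", "end")]
      } else {
        meth_iv <- rep_iv[take, c("start", "end")]
      }
      meth_iv <- meth_iv[order(meth_iv$start), , drop = FALSE]
      row.names(meth_iv) <- NULL
    }

    genome <- structure(
      list(name = name,
           sequence = random_dna(length),
           gene_intervals = gene_iv,
           repeat_intervals = rep_iv,
           methylated_intervals = meth_iv),
      class = "GenomeModel")
    validate_genome(genome)
    genome
  })
}

validate_genome <- function(genome) {
  stopifnot(inherits(genome, "GenomeModel"))
  len <- nchar(genome$sequence)
  validate_intervals(genome$gene_intervals, len, "gene")
  validate_intervals(genome$repeat_intervals, len, "repeat")
  validate_intervals(genome$methylated_intervals, len, "methylated")
  # gene and methylated intervals each mutually non-overlapping
  for (f in c("gene_intervals", "methylated_intervals")) {
    iv <- genome[[f]]
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)])) {
      stop(f, " overlap each other", call. = FALSE)
    }
  }
  invisible(genome)
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf(
    "GenomeModel '%s': %d bp | gene %d bp (%d ivs) | repeat %d bp (%d ivs) | methylated %d bp | hypomethylated %d bp\n",
    x$name, nchar(x$sequence),
    interval_total_bp(x$gene_intervals), nrow(x$gene_intervals),
    interval_total_bp(x$repeat_intervals), nrow(x$repeat_intervals),
    interval_total_bp(x$methylated_intervals), hypomethylated_size(x)))
  invisible(x)
}

#' Hypomethylated space of a simulated genome, in bp
#'
#' @param genome a `GenomeModel`.
#' @return genome length minus total methylated bp.
#' @export
hypomethylated_size <- function(genome) {
  nchar(genome$sequence) - interval_total_bp(genome$methylated_intervals)
}

#' Simulate a filtered or unfiltered read library
#'
#' Unfiltered reads start uniformly over the genome. Filtered reads are drawn
#' the same way but any candidate overlapping a methylated interval is
#' rejected and resampled -- modelling methylation filtration as a restriction
#' to the hypomethylated genome space -- except that each such candidate is
#' retained anyway with probability `leak_prob` (imperfect filtration by the
#' cloning strain). True origins are recorded for recovery tests.
#'
#' @param genome a `GenomeModel`.
#' @param kind `"filtered"` or `"unfiltered"`.
#' @param n_reads number of reads to draw.
#' @param read_len_range length-2 integer vector; read lengths are uniform on
#'   this range. Default `c(60, 140)` mirrors a 0.6-1.4 kb size-selection
#'   window scaled down tenfold for desk-scale tests.
#' @param leak_prob probability a methylated-overlapping candidate escapes
#'   filtration (default 0.05; ignored for unfiltered libraries).
#' @param seed integer seed.
#' @return a `ReadLibrary`: list with `reads` (data.frame: id, sequence,
#'   origin_start, origin_end, strand), `library_kind`, `seed`, `params`.
#' @export
simulate_library <- function(genome, kind = c("filtered", "unfiltered"),
                             n_reads, read_len_range = c(60L, 140L),
                             leak_prob = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(genome, "GenomeModel"), n_reads >= 0)
  glen <- nchar(genome$sequence)
  read_len_range <- as.integer(round(read_len_range))
  if (length(read_len_range) != 2L || any(read_len_range < 1L) ||
      read_len_range[1L] > read_len_range[2L] ||
      read_len_range[2L] > glen) {
    stop("read_len_range must satisfy 1 <= min <= max <= genome length",
         call. = FALSE)
  }
  if (leak_prob < 0 || leak_prob > 1) stop("leak_prob must be in [0, 1]",
                                           call. = FALSE)
  n_reads <- as.integer(n_reads)
  meth <- genome$methylated_intervals

  with_seed(derive_seed(seed, 211L), {
    draw <- function(n) {
      len <- sample.int(read_len_range[2L] - read_len_range[1L] + 1L, n,
                        replace = TRUE) + read_len_range[1L] - 1L
      start <- floor(runif(n) * (glen - len + 1L))
      data.frame(start = as.integer(start), end = as.integer(start + len))
    }
    if (n_reads == 0L) {
      acc <- new_intervals()
    } else if (kind == "unfiltered") {
      acc <- draw(n_reads)
    } else {
      acc <- NULL
      need <- n_reads
      while (need > 0L) {
        cand <- draw(need)
        bad <- overlaps_any(cand, meth)
        keep <- !bad | (runif(nrow(cand)) < leak_prob)
        acc <- rbind(acc, cand[keep, , drop = FALSE])
        need <- n_reads - nrow(acc)
      }
      row.names(acc) <- NULL
    }
    strand <- if (n_reads > 0L) sample(c("+", "-"), n_reads, replace = TRUE)
              else character()
    seqs <- if (n_reads > 0L) substring(genome$sequence, acc$start + 1L,
                                        acc$end)
            else character()
    if (any(strand == "-")) seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    reads <- data.frame(
      id = sprintf("%s_%s_%06d", genome$name,
                   if (kind == "filtered") "MF" else "UF",
                   seq_len(n_reads)),
      sequence = seqs,
      origin_start = acc$start, origin_end = acc$end,
      strand = strand, stringsAsFactors = FALSE)
    structure(
      list(reads = reads, library_kind = kind, seed = seed,
           params = list(n_reads = n_reads, read_len_range = read_len_range,
                         leak_prob = if (kind == "filtered") leak_prob else NA_real_)),
      class = "ReadLibrary")
  })
}

#' @export
print.ReadLibrary <- function(x, ...) {
  cat(sprintf("ReadLibrary (%s): %d reads, lengths %d-%d, seed %s\n",
              x$library_kind, nrow(x$reads), x$params$read_len_range[1L],
              x$params$read_len_range[2L], format(x$seed)))
  invisible(x)
}

#' Plant biallelic variants into a simulated genome
#'
#' Draws `n_sites` unique positions and assigns each a ref allele (the genome
#' base) and a distinct alt allele. The substitution spectrum is controlled
#' by `ti_weight`/`tv_weight`: each site is a transition with probability
#' `ti_weight / (ti_weight + tv_weight)` (alt = the transition partner of
#' ref), else a transversion with the two candidate alt bases equiprobable.
#' To plant a target Ti/Tv ratio r, set `ti_weight = r, tv_weight = 1`.
#'
#' @param genome a `GenomeModel`.
#' @param n_sites number of variant sites (<= genome length).
#' @param alt_fraction expected alt-allele frequency carried by reads built
#'   over these sites (recorded; used by [build_pileups()]).
#' @param ti_weight,tv_weight non-negative spectrum weights (not both zero).
#' @param seed integer seed.
#' @return data.frame with columns `position` (0-based, sorted, unique),
#'   `ref`, `alt`, `alt_fraction`, and attribute `ti_weight`/`tv_weight`.
#' @export
inject_variants <- function(genome, n_sites, alt_fraction = 0.5,
                            ti_weight = 1, tv_weight = 1, seed = 1L) {
  stopifnot(inherits(genome, "GenomeModel"))
  glen <- nchar(genome$sequence)
  if (n_sites < 0 || n_sites > glen) {
    stop("n_sites must lie in [0, genome length]", call. = FALSE)
  }
  if (ti_weight < 0 || tv_weight < 0 || ti_weight + tv_weight <= 0) {
    stop("spectrum weights must be non-negative and not both zero",
         call. = FALSE)
  }
  if (alt_fraction <= 0 || alt_fraction > 1) {
    stop("alt_fraction must be in (0, 1]", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  if (n_sites == 0L) {
    out <- data.frame(position = integer(), ref = character(),
                      alt = character(), alt_fraction = numeric())
    return(out)
  }
  transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
  with_seed(derive_seed(seed, 307L), {
    pos <- sort(sample.int(glen, n_sites) - 1L)
    ref <- strsplit(substring(genome$sequence, 1L, glen), "")[[1L]][pos + 1L]
    is_ti <- runif(n_sites) < ti_weight / (ti_weight + tv_weight)
    alt <- character(n_sites)
    alt[is_ti] <- transition_partner[ref[is_ti]]
    if (any(!is_ti)) {
      tv_choices <- lapply(ref[!is_ti], function(b) {
        setdiff(DNA_BASES, c(b, transition_partner[[b]]))
      })
      pick <- ceiling(runif(sum(!is_ti)) * 2)
      alt[!is_ti] <- mapply(function(ch, i) ch[i], tv_choices, pick)
    }
    data.frame(position = pos, ref = ref, alt = alt,
               alt_fraction = alt_fraction)
  })
}

#' Build multi-read pileup alignments carrying planted variants
#'
#' Tiles the genome into contig windows, covers each window with reads at
#' Poisson depth around `depth_mean`, gives each read the alt allele at each
#' overlapped variant site independently with probability `alt_fraction`, and
#' adds uniform substitution errors at `error_rate`. Reads are gap-free, so
#' columns align directly to contig coordinates; the result can be serialized
#' to the simplified ACE dialect of [write_ace()].
#'
#' @param genome a `GenomeModel`.
#' @param variants truth table from [inject_variants()] (may have 0 rows).
#' @param depth_mean mean read depth per column (>= 1).
#' @param error_rate per-base substitution error probability.
#' @param read_len read length in bp.
#' @param contig_len window length per contig.
#' @param n_contigs number of windows to realise (default: tile the whole
#'   genome).
#' @param seed integer seed.
#' @return list of `PileupAlignment` objects (see [read_ace()]), each with
#'   `contig_id`, `consensus`, and `reads` (id, start offset, sequence).
#' @export
build_pileups <- function(genome, variants, depth_mean = 8, error_rate = 0.0,
                          read_len = 100L, contig_len = 500L,
                          n_contigs = NULL, seed = 1L) {
  stopifnot(inherits(genome, "GenomeModel"))
  if (depth_mean < 1) stop("depth_mean must be >= 1", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  glen <- nchar(genome$sequence)
  contig_len <- as.integer(contig_len)
  read_len <- as.integer(read_len)
  if (read_len > contig_len) stop("read_len must be <= contig_len",
                                  call. = FALSE)
  starts <- seq(0L, glen - contig_len, by = contig_len)
  if (!is.null(n_contigs)) starts <- head(starts, n_contigs)

  with_seed(derive_seed(seed, 401L), {
    lapply(seq_along(starts), function(ci) {
      cstart <- starts[[ci]]
      consensus <- substring(genome$sequence, cstart + 1L, cstart + contig_len)
      v <- variants[variants$position >= cstart &
                    variants$position < cstart + contig_len, , drop = FALSE]
      # enough reads that expected column depth ~ depth_mean
      n_reads <- max(2L, rpois(1L, depth_mean * contig_len / read_len))
      rstart <- sort(as.integer(floor(runif(n_reads) *
                                        (contig_len - read_len + 1L))))
      seqs <- vapply(rstart, function(s) {
        bases <- strsplit(substring(consensus, s + 1L, s + read_len), "")[[1L]]
        if (nrow(v) > 0L) {
          local_pos <- v$position - cstart
          hit <- which(local_pos >= s & local_pos < s + read_len)
          for (h in hit) {
            if (runif(1L) < v$alt_fraction[h]) {
              bases[local_pos[h] - s + 1L] <- v$alt[h]
            }
          }
        }
        if (error_rate > 0) {
          err <- runif(read_len) < error_rate
          if (any(err)) {
            bases[err] <- vapply(bases[err], function(b) {
              sample(setdiff(DNA_BASES, b), 1L)
            }, character(1L))
          }
        }
        paste(bases, collapse = "")
      }, character(1L))
      structure(
        list(contig_id = sprintf("%s_ctg%05d", genome$name, ci),
             consensus = consensus,
             reads = data.frame(
               id = sprintf("%s_ctg%05d_r%04d", genome$name, ci,
                            seq_len(n_reads)),
               start = rstart, sequence = seqs, stringsAsFactors = FALSE)),
        class = "PileupAlignment")
    })
  })
}
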