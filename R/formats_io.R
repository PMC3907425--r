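# Readers/writers for the formats the pipeline touches. Coordinates are
# 0-based half-open internally; the +1 shift to 1-based closed coordinates
# happens exactly once, here, at serialization. All writers are
# deterministic: identical records give byte-identical files.

#' Read a FASTA file
#'
#' Backed by [Biostrings::readBStringSet()] with strict validation: any
#' character outside the IUPAC set `{A,C,G,T,N}` (after case folding) is a
#' format error naming the offending record. Lowercase bases are uppercased
#' with a logged warning.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  low <- grepl("[acgtn]", seqs)
  if (any(low)) {
    mf_log("warn", "read_fasta: uppercased lowercase bases in %d record(s)",
           sum(low))
    warning("lowercase bases uppercased in record(s): ",
            paste(head(ids[low], 5L), collapse = ", "), call. = FALSE)
    seqs <- toupper(seqs)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    stop(sprintf("read_fasta: non-IUPAC character '%s' in record '%s' (%s)",
                 ch, ids[i], path), call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write sequences as wrapped FASTA
#'
#' @param records named character vector (or a `ReadLibrary`); must be
#'   non-empty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "ReadLibrary")) {
    records <- setNames(records$reads$sequence, records$reads$id)
  }
  if (length(records) == 0L) stop("write_fasta: no records", call. = FALSE)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("write_fasta: all records must be named", call. = FALSE)
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# --- ACE (documented subset: AS/CO/AF/RD; pads '*'; QA/BQ ignored) ---------

#' Write pileup alignments in a simplified ACE dialect
#'
#' Emits `AS`, then per contig a `CO` record with the consensus, `AF` lines
#' giving each read's 1-based padded start on the contig, and `RD` records
#' with the read sequences. Pad characters are written as `*`. Only gap-free
#' reads produced by [build_pileups()] or parsed by [read_ace()] are
#' supported.
#'
#' @param pileups list of `PileupAlignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ace <- function(pileups, path) {
  wrap <- function(s) {
    if (nchar(s) == 0L) return(character())
    substring(s, seq(1L, nchar(s), 50L),
              pmin(seq(1L, nchar(s), 50L) + 49L, nchar(s)))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  n_reads <- sum(vapply(pileups, function(p) nrow(p$reads), integer(1L)))
  writeLines(sprintf("AS %d %d", length(pileups), n_reads), con)
  for (p in pileups) {
    writeLines("", con)
    writeLines(sprintf("CO %s %d %d 1 U", p$contig_id, nchar(p$consensus),
                       nrow(p$reads)), con)
    writeLines(wrap(gsub("-", "*", p$consensus, fixed = TRUE)), con)
    writeLines("", con)
    for (i in seq_len(nrow(p$reads))) {
      writeLines(sprintf("AF %s U %d", p$reads$id[i], p$reads$start[i] + 1L),
                 con)
    }
    for (i in seq_len(nrow(p$reads))) {
      writeLines("", con)
      writeLines(sprintf("RD %s %d 0 0", p$reads$id[i],
                         nchar(p$reads$sequence[i])), con)
      writeLines(wrap(gsub("-", "*", p$reads$sequence[i], fixed = TRUE)), con)
    }
  }
  invisible(path)
}

#' Read the supported ACE subset into pileup alignments
#'
#' Parses `CO`/`AF`/`RD` records; pads (`*`) are converted to `-`; each
#' read's padded offset is resolved to contig coordinates. `AF` records
#' without a matching `RD` (or vice versa), negative offsets, and truncated
#' files are format errors -- there is no silent partial parse.
#'
#' @param path path to an ACE file in the supported dialect.
#' @return list of `PileupAlignment` objects.
#' @export
read_ace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  fail <- function(fmt, ...) stop(sprintf(paste0("read_ace: ", fmt), ...),
                                  call. = FALSE)
  i <- 1L
  n <- length(lines)
  skip_blank <- function(i) { while (i <= n && !nzchar(lines[i])) i <- i + 1L; i }
  i <- skip_blank(i)
  if (i > n || !startsWith(lines[i], "AS ")) fail("missing AS header")
  i <- i + 1L
  read_seq <- function(i) {
    parts <- character()
    while (i <= n && nzchar(lines[i]) &&
           !grepl("^(CO|AF|RD|QA|AS|BQ) ", lines[i])) {
      parts <- c(parts, lines[i]); i <- i + 1L
    }
    list(seq = paste(parts, collapse = ""), i = i)
  }
  pileups <- list()
  while ((i <- skip_blank(i)) <= n) {
    if (!startsWith(lines[i], "CO ")) fail("expected CO record at line %d", i)
    co <- strsplit(lines[i], "\\s+")[[1L]]
    if (length(co) < 4L) fail("malformed CO record at line %d", i)
    contig_id <- co[2L]
    n_expect <- as.integer(co[4L])
    i <- skip_blank(i + 1L)
    sq <- read_seq(i); i <- sq$i
    if (!nzchar(sq$seq)) fail("contig %s has no consensus", contig_id)
    consensus <- gsub("*", "-", toupper(sq$seq), fixed = TRUE)
    af <- list(); rd <- list()
    repeat {
      i <- skip_blank(i)
      if (i > n || startsWith(lines[i], "CO ")) break
      if (startsWith(lines[i], "AF ")) {
        f <- strsplit(lines[i], "\\s+")[[1L]]
        if (length(f) < 4L) fail("malformed AF at line %d", i)
        off <- as.integer(f[4L]) - 1L
        if (is.na(off) || off < 0L) fail("negative or bad offset in AF at line %d", i)
        af[[f[2L]]] <- off
        i <- i + 1L
      } else if (startsWith(lines[i], "RD ")) {
        f <- strsplit(lines[i], "\\s+")[[1L]]
        if (length(f) < 2L) fail("malformed RD at line %d", i)
        sq <- read_seq(skip_blank(i + 1L)); i <- sq$i
        if (!nzchar(sq$seq)) fail("RD %s has no sequence", f[2L])
        rd[[f[2L]]] <- gsub("*", "-", toupper(sq$seq), fixed = TRUE)
      } else if (startsWith(lines[i], "QA ") || startsWith(lines[i], "BQ")) {
        i <- i + 1L  # tolerated, ignored
      } else {
        fail("unsupported record at line %d: %s", i, substr(lines[i], 1L, 20L))
      }
    }
    if (!setequal(names(af), names(rd))) {
      fail("contig %s: AF/RD records do not match (%d AF vs %d RD)",
           contig_id, length(af), length(rd))
    }
    if (length(rd) != n_expect) {
      fail("contig %s: expected %d reads, found %d (truncated file?)",
           contig_id, n_expect, length(rd))
    }
    ids <- names(af)[order(unlist(af[names(af)]), names(af))]
    pileups[[length(pileups) + 1L]] <- structure(
      list(contig_id = contig_id, consensus = consensus,
           reads = data.frame(id = ids,
                              start = unlist(af[ids], use.names = FALSE),
                              sequence = unlist(rd[ids], use.names = FALSE),
                              stringsAsFactors = FALSE)),
      class = "PileupAlignment")
  }
  pileups
}

#' Per-column base observations of a pileup
#'
#' @param pileup a `PileupAlignment`.
#' @return list (one element per contig position) of named character vectors
#'   `read id -> base`; bases include `-` (pad) and `N`.
#' @export
pileup_columns <- function(pileup) {
  stopifnot(inherits(pileup, "PileupAlignment"))
  ncol <- nchar(pileup$consensus)
  cols <- rep(list(character()), ncol)
  if (nrow(pileup$reads) == 0L) return(cols)
  lens <- nchar(pileup$reads$sequence)
  pos <- rep(pileup$reads$start, lens) + sequence(lens)  # 1-based column
  base <- setNames(unlist(strsplit(pileup$reads$sequence, ""),
                          use.names = FALSE),
                   rep(pileup$reads$id, lens))
  keep <- pos >= 1L & pos <= ncol
  got <- split(base[keep], pos[keep])
  cols[as.integer(names(got))] <- got
  cols
}

# base-count matrix (rows = contig positions, cols = A,C,G,T,N,-) plus depth;
# the fast substrate for SNP calling.
pileup_count_matrix <- function(pileup) {
  ncol <- nchar(pileup$consensus)
  lv <- c(DNA_BASES, "N", "-")
  if (nrow(pileup$reads) == 0L) {
    m <- matrix(0L, nrow = ncol, ncol = length(lv),
                dimnames = list(NULL, lv))
    return(m)
  }
  lens <- nchar(pileup$reads$sequence)
  pos <- rep(pileup$reads$start, lens) + sequence(lens)
  base <- unlist(strsplit(pileup$reads$sequence, ""), use.names = FALSE)
  keep <- pos >= 1L & pos <= ncol
  unclass(table(factor(pos[keep], levels = seq_len(ncol)),
                factor(base[keep], levels = lv)))
}

# --- tabular writers -------------------------------------------------------

#' Write SNP records as a minimal VCF 4.2 file
#'
#' One data line per record, sorted by (contig, position); internal 0-based
#' positions become 1-based POS. Duplicate (contig, position) keys are a
#' validation error.
#'
#' @param snps data.frame from [call_snps()] (columns `contig_id`,
#'   `position`, `allele_a`, `allele_b`, `depth`, `support_a`, `support_b`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=methylfiltr",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Column depth\">",
    "##INFO=<ID=SR,Number=2,Type=Integer,Description=\"Reads supporting REF,ALT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(snps) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  key <- paste(snps$contig_id, snps$position)
  if (anyDuplicated(key)) {
    stop("write_vcf: duplicate (contig, position) records", call. = FALSE)
  }
  snps <- snps[order(snps$contig_id, snps$position), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;SR=%d,%d",
                  snps$contig_id, snps$position + 1L, snps$allele_a,
                  snps$allele_b, snps$depth, snps$support_a, snps$support_b)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write features as GFF3
#'
#' Backed by [rtracklayer::export.gff3()]. Internal 0-based half-open
#' intervals become 1-based closed on output.
#'
#' @param features data.frame with columns `seqid`, `start`, `end` (0-based
#'   half-open), `type`, and optionally `strand`, `score`, plus any further
#'   columns, which become GFF3 attributes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  required <- c("seqid", "start", "end", "type")
  if (!all(required %in% names(features))) {
    stop("write_gff3: features need columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  features <- features[order(features$seqid, features$start, features$end), ,
                       drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = if ("strand" %in% names(features)) features$strand else "*")
  gr$type <- features$type
  if ("score" %in% names(features)) gr$score <- features$score
  extra <- setdiff(names(features),
                   c("seqid", "start", "end", "type", "strand", "score"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- features[[col]]
  gr$source <- "methylfiltr"
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Write a data.frame as a TSV with header
#'
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated hit table into HitRecords
#'
#' Accepts either a headered TSV with the internal column names or a
#' headerless 12-column BLAST outfmt-6-like table (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore, 1-based
#' closed coordinates, converted here to 0-based half-open).
#'
#' @param path path to the table.
#' @return data.frame of hit records: `query_id`, `target_id`,
#'   `query_start`, `query_end`, `target_start`, `target_end` (0-based
#'   half-open), `percent_identity`, `score`, `evalue`.
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("query_id", first)) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (ncol(df) != 12L) {
      stop("read_hits_tsv: expected 12 columns, got ", ncol(df),
           call. = FALSE)
    }
    df <- data.frame(
      query_id = df[[1L]], target_id = df[[2L]],
      query_start = pmin(df[[7L]], df[[8L]]) - 1L,
      query_end = pmax(df[[7L]], df[[8L]]),
      target_start = pmin(df[[9L]], df[[10L]]) - 1L,
      target_end = pmax(df[[9L]], df[[10L]]),
      percent_identity = df[[3L]], score = df[[12L]], evalue = df[[11L]],
      stringsAsFactors = FALSE)
  }
  validate_hits(df)
  df
}

validate_hits <- function(hits) {
  need <- c("query_id", "target_id", "query_start", "query_end",
            "target_start", "target_end", "percent_identity", "score")
  if (!all(need %in% names(hits))) {
    stop("hit table lacks columns: ",
         paste(setdiff(need, names(hits)), collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) > 0L) {
    if (any(hits$query_end <= hits$query_start) ||
        any(hits$target_end <= hits$target_start)) {
      stop("hit intervals must be non-empty", call. = FALSE)
    }
    if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
      stop("percent_identity must be in [0, 100]", call. = FALSE)
    }
    if (!is.null(hits$evalue) && any(hits$evalue < 0, na.rm = TRUE)) {
      stop("evalue must be >= 0", call. = FALSE)
    }
  }
  invisible(hits)
}
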