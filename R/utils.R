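# Internal helpers shared across modules: interval arithmetic on 0-based
# half-open data.frames with columns start/end, seeded RNG streams, rounding
# and logging.

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; survey-size reporting in this
#' package rounds half away from zero so that e.g. `1800/3.2 = 562.5`
#' reports as 563 Mb.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(562.5)  # 563
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Truncate (not round) to `digits` decimals; display convention for Ti/Tv.
truncate_decimal <- function(x, digits = 2L) {
  m <- 10^digits
  trunc(x * m) / m
}

# Derive a per-operation RNG seed from a top-level seed and a fixed stream
# offset, staying below 2^31 so it is a valid R integer.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 2654435761 + offset * 40503) %% 2147483647)
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- interval helpers (0-based half-open data.frames: start, end) ----------

new_intervals <- function(start = integer(), end = integer()) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

validate_intervals <- function(iv, len, what = "interval") {
  if (nrow(iv) == 0L) return(invisible(iv))
  if (any(iv$start < 0L) || any(iv$end > len) || any(iv$start >= iv$end)) {
    stop(sprintf("%s set violates 0 <= start < end <= %d", what, len),
         call. = FALSE)
  }
  invisible(iv)
}

interval_total_bp <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  sum(iv$end - iv$start)
}

# bp of the union of possibly-overlapping intervals
interval_union_bp <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  sum(IRanges::width(r))
}

# TRUE for each query interval that overlaps (>= 1 bp) any subject interval
overlaps_any <- function(q, s) {
  if (nrow(q) == 0L) return(logical(0))
  if (nrow(s) == 0L) return(rep(FALSE, nrow(q)))
  IRanges::overlapsAny(
    IRanges::IRanges(start = q$start + 1L, end = q$end),
    IRanges::IRanges(start = s$start + 1L, end = s$end)
  )
}

# --- logging ---------------------------------------------------------------

.mf_log_levels <- c(debug = 10L, info = 20L, warn = 30L, quiet = 90L)

#' Set the package log level
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return the previous level, invisibly.
#' @export
mf_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  old <- getOption("methylfiltr.log_level", "warn")
  options(methylfiltr.log_level = level)
  invisible(old)
}

mf_log <- function(level, fmt, ...) {
  cur <- getOption("methylfiltr.log_level", "warn")
  if (.mf_log_levels[[level]] >= .mf_log_levels[[cur]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# --- small sequence helpers ------------------------------------------------

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
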