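# Filter power (FP) and effective sampled genome size. Two estimators:
# the direct gene-hit probability ratio, and an inversion of a piecewise
# Lander-Waterman island-count expectation for a mixed assembly of filtered
# and unfiltered reads.

new_fp_estimate <- function(fp, genome_size, method, inputs_summary,
                            se = NA_real_, no_solution = FALSE,
                            all_roots = numeric()) {
  structure(list(fp = fp, genome_size = genome_size,
                 sampled_size = if (is.na(fp)) NA_real_ else genome_size / fp,
                 method = method, se = se, no_solution = no_solution,
                 all_roots = all_roots, inputs_summary = inputs_summary),
            class = "FilterPowerEstimate")
}

#' @export
print.FilterPowerEstimate <- function(x, ...) {
  if (x$no_solution) {
    cat(sprintf("FilterPowerEstimate (%s): no solution\n", x$method))
  } else {
    cat(sprintf(
      "FilterPowerEstimate (%s): FP = %.3g%s | genome %s -> sampled %s\n",
      x$method, x$fp,
      if (is.na(x$se)) "" else sprintf(" (s.e. %.3g)", x$se),
      format(x$genome_size, big.mark = ","),
      format(round_half_away(x$sampled_size), big.mark = ",")))
  }
  invisible(x)
}

#' Direct filter-power estimate from gene-hit counts
#'
#' FP is the probability that a filtered read sampled gene sequence divided
#' by the same probability for an unfiltered read:
#' `(filtered_hits/filtered_total) / (unfiltered_hits/unfiltered_total)`.
#' A delta-method standard error for the binomial-proportion ratio is
#' attached for reporting.
#'
#' @param filtered_hits,filtered_total gene-hitting and total reads in the
#'   filtered library.
#' @param unfiltered_hits,unfiltered_total same for the unfiltered library.
#' @param genome_size genome size (any unit; sampled size is reported in the
#'   same unit). Default 1 (so `sampled_size` is a fraction).
#' @return a `FilterPowerEstimate` with `method = "direct"`.
#' @export
#' @examples
#' direct_filter_power(40, 100, 20, 100)$fp  # 2
direct_filter_power <- function(filtered_hits, filtered_total,
                                unfiltered_hits, unfiltered_total,
                                genome_size = 1) {
  if (filtered_total <= 0 || unfiltered_total <= 0) {
    stop("library totals must be positive", call. = FALSE)
  }
  if (filtered_hits < 0 || filtered_hits > filtered_total ||
      unfiltered_hits < 0 || unfiltered_hits > unfiltered_total) {
    stop("hits must lie in [0, total]", call. = FALSE)
  }
  if (unfiltered_hits == 0) {
    stop("unfiltered hit rate is zero: filter power undefined", call. = FALSE)
  }
  p1 <- filtered_hits / filtered_total
  p2 <- unfiltered_hits / unfiltered_total
  fp <- p1 / p2
  # var(log fp) ~ (1-p1)/(n1 p1) + (1-p2)/(n2 p2)
  vlog <- (1 - p1) / (filtered_total * p1) +
    (1 - p2) / (unfiltered_total * p2)
  new_fp_estimate(fp, genome_size, "direct",
                  inputs_summary = list(
                    filtered_hits = filtered_hits,
                    filtered_total = filtered_total,
                    unfiltered_hits = unfiltered_hits,
                    unfiltered_total = unfiltered_total),
                  se = fp * sqrt(vlog))
}

#' Direct filter power measured on simulated libraries
#'
#' Counts, in each library, the reads whose true origin overlaps a gene
#' interval, and feeds the four counts to [direct_filter_power()].
#'
#' @param genome the `GenomeModel` the libraries were drawn from.
#' @param filtered,unfiltered `ReadLibrary` objects.
#' @return a `FilterPowerEstimate`.
#' @export
direct_filter_power_sim <- function(genome, filtered, unfiltered) {
  stopifnot(inherits(filtered, "ReadLibrary"),
            inherits(unfiltered, "ReadLibrary"))
  hit <- function(lib) {
    q <- data.frame(start = lib$reads$origin_start,
                    end = lib$reads$origin_end)
    sum(overlaps_any(q, genome$gene_intervals))
  }
  direct_filter_power(hit(filtered), nrow(filtered$reads),
                      hit(unfiltered), nrow(unfiltered$reads),
                      genome_size = nchar(genome$sequence))
}

#' Sampled genome space given genome size and filter power
#'
#' @param genome_size genome size in Mb.
#' @param fp filter power (> 0).
#' @param round if `TRUE` (default), round half away from zero to integer Mb
#'   for reporting.
#' @return sampled size `genome_size / fp` in Mb.
#' @export
#' @examples
#' genome_space(1800, 2.8)  # 643
genome_space <- function(genome_size, fp, round = TRUE) {
  if (!is.numeric(fp) || any(fp <= 0)) stop("fp must be > 0", call. = FALSE)
  out <- genome_size / fp
  if (round) round_half_away(out) else out
}

#' Genome reduction achieved by filtration
#'
#' @param genome_size genome size in Mb.
#' @param sampled_size hypomethylated space actually sampled, in Mb.
#' @return list with `filtered_out` (Mb) and `reduction_pct` (integer %).
#' @export
#' @examples
#' reduction_stats(1800, 705)  # 1095 Mb filtered out, 61 %
reduction_stats <- function(genome_size, sampled_size) {
  if (sampled_size <= 0 || sampled_size > genome_size) {
    stop("sampled_size must lie in (0, genome_size]", call. = FALSE)
  }
  filtered_out <- genome_size - sampled_size
  list(filtered_out = filtered_out,
       reduction_pct = round_half_away(100 * filtered_out / genome_size))
}

#' Expected island count in a mixed filtered/unfiltered assembly
#'
#' Piecewise Lander-Waterman expectation. Filtered reads fall only in the
#' hypomethylated space of size `filtered_size` (G_f); unfiltered reads fall
#' uniformly over the whole genome `genome_size` (G). Read-start densities
#' are therefore `lambda_in = n_filtered/G_f + n_unfiltered/G` inside the
#' hypomethylated space and `lambda_out = n_unfiltered/G` outside, and with
#' effective length `L - T` (a join needs a detectable overlap of at least
#' `T` bp) the expected number of islands is
#'
#' `lambda_in * G_f * exp(-lambda_in (L-T)) +
#'  lambda_out * (G - G_f) * exp(-lambda_out (L-T))`.
#'
#' At `n_filtered = 0` or `filtered_size = genome_size` this reduces to the
#' classic single-genome formula `n * exp(-n (L-T) / G)`.
#'
#' @param n_filtered,n_unfiltered reads per library.
#' @param read_len read length L in bp.
#' @param min_overlap minimum detectable overlap T in bp (`L > T >= 0`).
#' @param genome_size genome size G in bp.
#' @param filtered_size hypomethylated size G_f in bp (`0 < G_f <= G`).
#' @return expected island count.
#' @export
expected_islands_mixed <- function(n_filtered, n_unfiltered, read_len,
                                   min_overlap, genome_size, filtered_size) {
  if (filtered_size <= 0 || filtered_size > genome_size) {
    stop("filtered_size must lie in (0, genome_size]", call. = FALSE)
  }
  if (min_overlap < 0 || read_len <= min_overlap) {
    stop("need read_len > min_overlap >= 0", call. = FALSE)
  }
  sigma <- read_len - min_overlap
  lam_in <- n_filtered / filtered_size + n_unfiltered / genome_size
  lam_out <- n_unfiltered / genome_size
  lam_in * filtered_size * exp(-lam_in * sigma) +
    lam_out * (genome_size - filtered_size) * exp(-lam_out * sigma)
}

#' Infer the filtered genome size from an observed island count
#'
#' Solves `expected_islands_mixed(G_f) = observed_islands` for G_f by a
#' coarse grid scan (1000 points over (0, G]) followed by bisection on each
#' bracketing interval; filter power is then `G / G_f`. If several roots
#' exist, the one whose FP is closest to `direct_fp` (when supplied),
#' otherwise the largest G_f (the most conservative FP), is reported; all
#' roots are kept in `all_roots`. If the observed count is outside the
#' attainable range the estimate carries `no_solution = TRUE` rather than
#' failing.
#'
#' The inversion needs at least `min_coverage` (default 0.1x) coverage of the
#' inferred filtered space to be reliable; below that it refuses with an
#' explicit insufficiency error.
#'
#' @param observed_islands islands observed in the mixed assembly
#'   (<= total reads).
#' @param n_filtered,n_unfiltered,read_len,min_overlap,genome_size as in
#'   [expected_islands_mixed()].
#' @param direct_fp optional direct-method FP used to pick among multiple
#'   roots.
#' @param min_coverage minimum filtered-space coverage `n_filtered * L / G_f`
#'   (default 0.1).
#' @return a `FilterPowerEstimate` with `method = "lander_waterman"`.
#' @export
infer_filtered_size <- function(observed_islands, n_filtered, n_unfiltered,
                                read_len, min_overlap, genome_size,
                                direct_fp = NULL, min_coverage = 0.1) {
  if (observed_islands > n_filtered + n_unfiltered) {
    stop("observed_islands cannot exceed the number of reads", call. = FALSE)
  }
  inputs <- list(observed_islands = observed_islands,
                 n_filtered = n_filtered, n_unfiltered = n_unfiltered,
                 read_len = read_len, min_overlap = min_overlap)
  f <- function(gf) {
    expected_islands_mixed(n_filtered, n_unfiltered, read_len, min_overlap,
                           genome_size, gf) - observed_islands
  }
  grid <- seq(genome_size / 1000, genome_size, length.out = 1000L)
  vals <- vapply(grid, f, numeric(1L))
  roots <- numeric()
  if (any(vals == 0)) roots <- grid[vals == 0]
  sign_change <- which(vals[-1L] * vals[-length(vals)] < 0)
  for (i in sign_change) {
    r <- uniroot(f, lower = grid[i], upper = grid[i + 1L],
                 tol = 1e-9 * genome_size)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    mf_log("info", "LW inversion: observed %d islands unattainable",
           observed_islands)
    return(new_fp_estimate(NA_real_, genome_size, "lander_waterman",
                           inputs, no_solution = TRUE))
  }
  if (length(roots) > 1L) {
    mf_log("info", "LW inversion: %d roots (%s)", length(roots),
           paste(signif(roots, 4), collapse = ", "))
  }
  gf <- if (length(roots) > 1L && !is.null(direct_fp)) {
    roots[which.min(abs(genome_size / roots - direct_fp))]
  } else {
    max(roots)
  }
  coverage <- n_filtered * read_len / gf
  if (coverage < min_coverage) {
    stop(sprintf(
      "sequence coverage insufficient for genome sampling analysis (%.3fx < %.2fx of the inferred filtered space)",
      coverage, min_coverage), call. = FALSE)
  }
  new_fp_estimate(genome_size / gf, genome_size, "lander_waterman",
                  inputs, all_roots = roots)
}

#' Monte-Carlo oracle for the mixed-assembly island expectation
#'
#' Places `n_filtered` read starts uniformly in a contiguous filtered
#' segment of size `filtered_size` and `n_unfiltered` uniformly over the
#' whole genome, clusters them with [cluster_islands()], and returns the
#' island counts over `n_rep` independent placements. Used to validate
#' [expected_islands_mixed()] without assuming its formula.
#'
#' Placements are continuous coordinates: the Lander-Waterman expectation
#' is a continuous-space model, and integer placements carry a small
#' (order `1/(L-T)`) systematic offset in the join probability that is
#' detectable at Monte-Carlo precision though negligible at the tolerances
#' of genome-size inference.
#'
#' @inheritParams expected_islands_mixed
#' @param n_rep number of replicate placements.
#' @param seed integer seed.
#' @return integer vector of island counts, length `n_rep`.
#' @export
mc_island_counts <- function(n_filtered, n_unfiltered, read_len, min_overlap,
                             genome_size, filtered_size, n_rep = 200L,
                             seed = 1L) {
  with_seed(derive_seed(seed, 509L), {
    vapply(seq_len(n_rep), function(rep) {
      sf <- runif(n_filtered) * (filtered_size - read_len)
      su <- runif(n_unfiltered) * (genome_size - read_len)
      starts <- c(sf, su)
      count_islands(data.frame(start = starts, end = starts + read_len),
                    min_overlap = min_overlap)
    }, integer(1L))
  })
}
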