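#' Intersection of two binder sets
#'
#' Exact set intersection with percentages of each parent set, rounded half
#' away from zero as printed in figure legends.
#'
#' @param a,b [binder_set] objects drawn from a shared universe.
#' @return A list of class `overlap_summary`: `size_a`, `size_b`,
#'   `size_intersection`, `pct_of_a`, `pct_of_b`, `universe_size`,
#'   `members`.
#' @examples
#' u <- paste0("t", 1:200)
#' a <- binder_set(u[1:50], 200)
#' b <- binder_set(u[26:105], 200)
#' intersect_binders(a, b)
#' @export
intersect_binders <- function(a, b) {
  stopifnot(inherits(a, "binder_set"), inherits(b, "binder_set"))
  if (length(a$members) == 0 || length(b$members) == 0) {
    stopf("percentage of an empty parent set is undefined")
  }
  common <- intersect(a$members, b$members)
  structure(list(
    size_a = length(a$members),
    size_b = length(b$members),
    size_intersection = length(common),
    pct_of_a = round_half_up(100 * length(common) / length(a$members)),
    pct_of_b = round_half_up(100 * length(common) / length(b$members)),
    universe_size = max(a$universe_size, b$universe_size),
    members = common), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap: |A|=%d, |B|=%d, |A&B|=%d (%d%% of A, %d%% of B)\n",
              x$size_a, x$size_b, x$size_intersection, x$pct_of_a, x$pct_of_b))
  invisible(x)
}

#' Share of the detected transcriptome in a binder set
#'
#' @param set A [binder_set].
#' @return Integer percentage `round(100 * |members| / universe_size)`,
#'   rounded half away from zero.
#' @examples
#' transcriptome_fraction(binder_set(paste0("t", 1:837), 12388))  # 7
#' @export
transcriptome_fraction <- function(set) {
  stopifnot(inherits(set, "binder_set"))
  round_half_up(100 * length(set$members) / set$universe_size)
}

#' CLIP peak coverage of a transcript set
#'
#' Counts how many transcripts in a query set have at least one CLIP/eCLIP
#' peak overlapping them by at least `min_overlap` bp, either anywhere in
#' the genomic span (`mode = "span"`) or within an exon (`mode = "exonic"`).
#' With `strand_mode = "matched"` a peak must lie on the transcript's strand
#' (strandless `*` peaks match either); `"ignore"` disregards strand.
#'
#' @param query A [binder_set] (or character vector of transcript ids).
#' @param peaks A `GRanges` of peaks, e.g. from [read_bed()].
#' @param transcripts A [transcript_table] covering every query transcript.
#' @param mode `"span"` (default) or `"exonic"`.
#' @param strand_mode `"matched"` (default) or `"ignore"`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return A list of class `coverage_summary`: `n_queried`, `n_covered`,
#'   `pct_covered` (rounded), `mode`, `strand_mode`, `covered_ids`.
#' @export
clip_coverage <- function(query, peaks, transcripts,
                          mode = c("span", "exonic"),
                          strand_mode = c("matched", "ignore"),
                          min_overlap = 1L) {
  mode <- match.arg(mode)
  strand_mode <- match.arg(strand_mode)
  ids <- if (inherits(query, "binder_set")) query$members else as.character(query)
  if (length(ids) == 0) stopf("empty query set")
  gr <- transcript_ranges(transcripts, ids, mode = mode)
  lev <- union(GenomeInfoDb::seqlevels(gr), GenomeInfoDb::seqlevels(peaks))
  GenomeInfoDb::seqlevels(gr) <- lev
  GenomeInfoDb::seqlevels(peaks) <- lev
  hits <- GenomicRanges::findOverlaps(gr, peaks,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = strand_mode == "ignore")
  covered <- unique(names(gr)[S4Vectors::queryHits(hits)])
  structure(list(
    n_queried = length(ids),
    n_covered = length(covered),
    pct_covered = round_half_up(100 * length(covered) / length(ids)),
    mode = mode,
    strand_mode = strand_mode,
    covered_ids = covered), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage (%s, strand %s): %d / %d transcripts (%d%%)\n",
              x$mode, x$strand_mode, x$n_covered, x$n_queried, x$pct_covered))
  invisible(x)
}

#' One-sample goodness-of-fit chi-square for a two-class count
#'
#' Pearson chi-square (1 df, no continuity correction) of an observed split
#' `k` of `n` against an expected proportion `p`: the test used to compare
#' the share of translationally shifted transcripts among protein-bound
#' mRNAs with the global share.
#'
#' @param k Observed count in the class of interest (`0 <= k <= n`).
#' @param n Total count (`>= 1`).
#' @param expected_proportion Expected proportion `p` in `(0, 1)`.
#' @return A list of class `chisq_gof`: `observed` (`c(k, n - k)`),
#'   `expected`, `statistic`, `df`, `p_value` (upper tail).
#' @examples
#' goodness_of_fit_chisq(70, 100, 0.5)$statistic  # 16
#' @export
goodness_of_fit_chisq <- function(k, n, expected_proportion) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  if (!is_count(k) || k > n) stopf("k must be an integer in [0, n]")
  p <- expected_proportion
  if (!is_scalar_number(p) || p <= 0 || p >= 1) {
    stopf("expected_proportion must lie strictly in (0, 1)")
  }
  expected <- c(n * p, n * (1 - p))
  if (any(expected == 0)) stopf("zero expected count")
  observed <- c(k, n - k)
  stat <- sum((observed - expected)^2 / expected)
  structure(list(observed = observed,
                 expected = expected,
                 statistic = stat,
                 df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "chisq_gof")
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf("chi-square GOF: X2 = %.4g, df = %d, p = %.3g (observed %d/%d)\n",
              x$statistic, x$df, x$p_value, x$observed[1], sum(x$observed)))
  invisible(x)
}
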