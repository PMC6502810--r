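#' Find poly-C tracts in a nucleotide sequence
#'
#' Scans a DNA/RNA sequence for maximal runs of cytosine of at least
#' `min_run` nucleotides. Poly-C tracts in 3' UTRs are the binding substrate
#' of poly-C-binding proteins such as hnRNPK; this scan locates candidate
#' sites. Matching is case-insensitive, `U` and `T` are equivalent, and `N`
#' never matches `C`.
#'
#' @param sequence A single string over `A`, `C`, `G`, `T`, `U`, `N`.
#' @param min_run Minimum tract length (positive integer).
#' @return A data frame with integer columns `start` and `end`
#'   (0-based half-open), one row per maximal tract, ordered left to right.
#' @examples
#' find_polyc_tracts("ACCCCA", min_run = 3)  # one tract at (1, 5)
#' @export
find_polyc_tracts <- function(sequence, min_run) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stopf("'sequence' must be a single string")
  }
  if (!is_count(min_run) || min_run < 1) stopf("min_run must be a positive integer")
  s <- chartr("u", "t", tolower(sequence))
  if (!grepl("^[acgtn]*$", s)) {
    stopf("sequence contains characters outside {A,C,G,T,U,N}")
  }
  empty <- data.frame(start = integer(0), end = integer(0))
  if (!nzchar(s)) return(empty)
  m <- gregexpr(sprintf("c{%d,}", min_run), s)[[1]]
  if (m[1] == -1) return(empty)
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}
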