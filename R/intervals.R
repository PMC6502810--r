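#' Read peak intervals from a BED file
#'
#' Reads BED3 or BED6 into a `GRanges`. BED is natively 0-based half-open;
#' the returned `GRanges` follows the Bioconductor 1-based closed
#' convention, so a BED line `chr1 10 20` becomes `chr1:11-20` (width 10).
#' Records without a strand field are strand-agnostic (`*`) and overlap
#' either strand in downstream queries.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` (possibly empty) with `name`/`score` metadata when
#'   present in the file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t| +")[[1]]
    if (length(f) < 3) stopf("BED line %d has fewer than 3 fields", lineno[i])
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stopf("non-numeric coordinate on BED line %d", lineno[i])
    if (s >= e) stopf("start >= end on BED line %d", lineno[i])
  }
  if (length(body) == 0) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "bed")
}

#' Write intervals as BED
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
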