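#' Transcript annotation table
#'
#' One row per transcript: identity, genomic span and exon structure. All
#' coordinates at this interface are 0-based half-open; GTF input/output is
#' converted on read/write. `length_nt` is the summed exon length when exons
#' are given, otherwise it must be supplied explicitly.
#'
#' @param transcript_id,gene_id Character vectors (required, no duplicates
#'   in `transcript_id`).
#' @param chrom Chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param span_start,span_end 0-based half-open genomic span.
#' @param exons List of two-column integer matrices (`start`, `end`; 0-based
#'   half-open), one per transcript, sorted and non-overlapping. Optional.
#' @param length_nt Explicit transcript lengths; required when `exons` is
#'   `NULL`, derived (and checked) otherwise.
#' @param gene_symbol Optional symbols.
#' @return A data frame of class `transcript_table` with columns
#'   `transcript_id`, `gene_id`, `gene_symbol`, `length_nt`, `chrom`,
#'   `strand`, `span_start`, `span_end` and a list-column `exons`.
#' @export
transcript_table <- function(transcript_id, gene_id, chrom, strand,
                             span_start, span_end, exons = NULL,
                             length_nt = NULL, gene_symbol = NA_character_) {
  n <- length(transcript_id)
  if (anyDuplicated(transcript_id)) {
    stopf("duplicate transcript_id: %s",
          transcript_id[duplicated(transcript_id)][1])
  }
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(span_start >= span_end)) {
    bad <- transcript_id[span_start >= span_end][1]
    stopf("span_start must be < span_end (transcript '%s')", bad)
  }
  if (is.null(exons)) {
    if (is.null(length_nt)) {
      stopf("either exons or an explicit length_nt must be supplied")
    }
    exons <- rep(list(NULL), n)
  } else {
    stopifnot(length(exons) == n)
    derived <- vapply(seq_len(n), function(i) {
      ex <- exons[[i]]
      if (is.null(ex)) return(NA_integer_)
      stopifnot(is.matrix(ex), ncol(ex) == 2)
      if (any(ex[, 1] >= ex[, 2])) {
        stopf("degenerate exon in transcript '%s'", transcript_id[i])
      }
      if (any(ex[, 1] < span_start[i]) || any(ex[, 2] > span_end[i])) {
        stopf("exon outside span in transcript '%s'", transcript_id[i])
      }
      if (nrow(ex) > 1) {
        if (is.unsorted(ex[, 1], strictly = TRUE) ||
            any(ex[-1, 1] < ex[-nrow(ex), 2])) {
          stopf("exons must be sorted and non-overlapping in transcript '%s'",
                transcript_id[i])
        }
      }
      as.integer(sum(ex[, 2] - ex[, 1]))
    }, integer(1))
    if (is.null(length_nt)) {
      length_nt <- derived
    } else if (any(!is.na(derived) & derived != length_nt)) {
      stopf("length_nt disagrees with summed exon length (transcript '%s')",
            transcript_id[which(!is.na(derived) & derived != length_nt)][1])
    }
  }
  if (any(is.na(length_nt) | length_nt < 1)) {
    stopf("length_nt must be a positive integer for every transcript")
  }
  out <- data.frame(transcript_id = as.character(transcript_id),
                    gene_id = as.character(gene_id),
                    gene_symbol = rep_len(as.character(gene_symbol), n),
                    length_nt = as.integer(length_nt),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    span_start = as.integer(span_start),
                    span_end = as.integer(span_end),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  rownames(out) <- out$transcript_id
  class(out) <- c("transcript_table", "data.frame")
  out
}

#' Read transcript models from a GTF file
#'
#' Parses exon features (Ensembl-style `transcript_id`/`gene_id` attributes)
#' into a [transcript_table]. GTF 1-based closed coordinates are converted to
#' the package's 0-based half-open convention; exons of each transcript are
#' sorted and overlapping exon records are merged.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_table].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stopf("no exon features in %s", path)
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id)) {
    stopf("exon feature without transcript_id in %s", path)
  }
  ids <- ex$transcript_id
  by_tx <- split(seq_along(ex), ids)
  tx_ids <- names(by_tx)
  n <- length(tx_ids)
  gene_id <- character(n)
  gene_symbol <- rep(NA_character_, n)
  chrom <- character(n)
  strand_v <- character(n)
  exon_list <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- ex[by_tx[[i]]]
    str <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(str) != 1 || !str %in% c("+", "-")) {
      stopf("mixed or missing strand within transcript '%s'", tx_ids[i])
    }
    chr <- unique(as.character(GenomicRanges::seqnames(sub)))
    if (length(chr) != 1) {
      stopf("exons of transcript '%s' on multiple chromosomes", tx_ids[i])
    }
    gid <- unique(sub$gene_id)
    if (length(gid) != 1 || is.na(gid)) {
      stopf("missing or inconsistent gene_id for transcript '%s'", tx_ids[i])
    }
    # merge overlapping exon records, keep abutting exons distinct
    r <- IRanges::reduce(IRanges::ranges(sub), min.gapwidth = 0L)
    exon_list[[i]] <- cbind(start = IRanges::start(r) - 1L,
                            end = IRanges::end(r))
    gene_id[i] <- gid
    if (!is.null(sub$gene_name)) gene_symbol[i] <- sub$gene_name[1]
    chrom[i] <- chr
    strand_v[i] <- str
  }
  span_start <- vapply(exon_list, function(e) e[1, 1], integer(1))
  span_end <- vapply(exon_list, function(e) e[nrow(e), 2], integer(1))
  transcript_table(tx_ids, gene_id, chrom, strand_v, span_start, span_end,
                   exons = exon_list, gene_symbol = gene_symbol)
}

#' Write a transcript table as GTF
#'
#' Emits one `exon` feature per exon, converting 0-based half-open
#' coordinates back to GTF's 1-based closed convention. Round-trips with
#' [read_gtf()].
#'
#' @param tt A [transcript_table] whose rows all carry exons.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tt, path) {
  stopifnot(inherits(tt, "transcript_table"))
  if (any(vapply(tt$exons, is.null, logical(1)))) {
    stopf("write_gtf requires exon structure for every transcript")
  }
  per_tx <- lapply(seq_len(nrow(tt)), function(i) {
    ex <- tt$exons[[i]]
    GenomicRanges::GRanges(
      seqnames = tt$chrom[i],
      ranges = IRanges::IRanges(start = ex[, 1] + 1L, end = ex[, 2]),
      strand = tt$strand[i],
      type = "exon",
      transcript_id = tt$transcript_id[i],
      gene_id = tt$gene_id[i])
  })
  gr <- suppressWarnings(do.call(c, per_tx))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Genomic ranges of transcripts
#'
#' Builds a `GRanges` for a set of transcripts, either one range per
#' transcript span or one range per exon (names give the owning transcript).
#'
#' @param tt A [transcript_table].
#' @param ids Transcript ids to extract (default: all).
#' @param mode `"span"` or `"exonic"`.
#' @return A `GRanges` whose names are transcript ids.
#' @export
transcript_ranges <- function(tt, ids = tt$transcript_id,
                              mode = c("span", "exonic")) {
  mode <- match.arg(mode)
  missing <- setdiff(ids, tt$transcript_id)
  if (length(missing)) {
    stopf("transcript(s) absent from annotation: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  }
  sub <- tt[ids, ]
  if (mode == "span") {
    gr <- GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$span_start + 1L, end = sub$span_end),
      strand = sub$strand)
    names(gr) <- sub$transcript_id
    return(gr)
  }
  if (any(vapply(sub$exons, is.null, logical(1)))) {
    stopf("exonic mode requires exon structure for every queried transcript")
  }
  n_ex <- vapply(sub$exons, nrow, integer(1))
  ex <- do.call(rbind, sub$exons)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(sub$chrom, n_ex),
    ranges = IRanges::IRanges(start = ex[, 1] + 1L, end = ex[, 2]),
    strand = rep(sub$strand, n_ex))
  names(gr) <- rep(sub$transcript_id, n_ex)
  gr
}
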