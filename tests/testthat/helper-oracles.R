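# independent brute-force oracles and tiny fixture builders,
# deliberately written without the package's own machinery

# half-open interval overlap of >= 1 bp
overlaps_halfopen <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

strand_compatible <- function(tx_strand, peak_strand, strand_mode) {
  if (strand_mode == "ignore") return(TRUE)
  peak_strand == "*" || peak_strand == tx_strand
}

# O(n * m) coverage loop over a transcript_table and a plain peak data frame
# (chrom, start, end, strand; 0-based half-open)
brute_force_coverage <- function(ids, tt, peaks_df, mode, strand_mode) {
  covered <- character(0)
  for (id in ids) {
    row <- tt[tt$transcript_id == id, ]
    ivs <- if (mode == "span") {
      matrix(c(row$span_start, row$span_end), ncol = 2)
    } else {
      row$exons[[1]]
    }
    hit <- FALSE
    for (j in seq_len(nrow(peaks_df))) {
      if (peaks_df$chrom[j] != row$chrom) next
      if (!strand_compatible(row$strand, peaks_df$strand[j], strand_mode)) next
      for (k in seq_len(nrow(ivs))) {
        if (overlaps_halfopen(ivs[k, 1], ivs[k, 2],
                              peaks_df$start[j], peaks_df$end[j])) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (hit) covered <- c(covered, id)
  }
  covered
}

# position-by-position scan for maximal C runs (0-based half-open)
brute_force_polyc <- function(s, min_run) {
  chars <- strsplit(chartr("Uu", "Tt", toupper(s)), "")[[1]]
  is_c <- chars == "C"
  out <- NULL
  i <- 1
  while (i <= length(chars)) {
    if (is_c[i]) {
      j <- i
      while (j < length(chars) && is_c[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) out <- rbind(out, c(i - 1, j))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(out)) {
    data.frame(start = integer(0), end = integer(0))
  } else {
    data.frame(start = as.integer(out[, 1]), end = as.integer(out[, 2]))
  }
}

# literal median-of-ratios definition, cell by cell
brute_force_size_factors <- function(m) {
  pos <- apply(m > 0, 1, all)
  sub <- m[pos, , drop = FALSE]
  geo <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(sub)),
         function(j) median(sub[, j] / geo),
         numeric(1))
}

write_counts_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gtf_fixture <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon_line <- function(chrom, start1, end1, strand, tx, gene = "g1",
                          attrs = sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)) {
  paste(chrom, "test", "exon", start1, end1, ".", strand, ".", attrs, sep = "\t")
}

# a small deterministic transcript table on one chromosome
toy_transcripts <- function() {
  transcript_table(
    transcript_id = c("tA", "tB"),
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    span_start = c(100L, 1000L),
    span_end = c(200L, 1400L),
    exons = list(cbind(start = 100L, end = 200L),
                 cbind(start = c(1000L, 1300L), end = c(1100L, 1400L))))
}

# GRanges built directly from a 0-based half-open peak data frame
peaks_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}
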