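#' Read a differential-expression result table
#'
#' TSV with columns `gene_id`, `log2fc` (knockout vs wild type) and `padj`.
#' One row per gene; `padj` must be present and in `[0, 1]`.
#'
#' @param path Path to the TSV.
#' @return Data frame of class `de_table`.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  as_de_table(df)
}

#' Validate a differential-expression table
#'
#' @param df Data frame with columns `gene_id`, `log2fc`, `padj`.
#' @return The validated data frame with class `de_table`.
#' @export
as_de_table <- function(df) {
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(df))) {
    stopf("DE table needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stopf("duplicate gene_id '%s' in DE table", df$gene_id[duplicated(df$gene_id)][1])
  }
  if (anyNA(df$padj) || any(df$padj < 0 | df$padj > 1)) {
    stopf("padj must be present and in [0, 1] for every gene")
  }
  class(df) <- unique(c("de_table", class(df)))
  df
}

#' Filter a DE table by FDR and fold change
#'
#' Retains genes with `padj <= fdr` and `|log2fc| >= log2(fold)` (both
#' thresholds inclusive) and records the direction of change
#' (`sign(log2fc)`).
#'
#' @param table A `de_table` (knockout vs wild-type contrast).
#' @param fdr Adjusted-p cutoff (default 0.05).
#' @param fold Fold-change cutoff on the linear scale, `>= 1` (default 2).
#' @return Data frame of class `de_gene_set` with columns `gene_id`,
#'   `log2fc`, `padj`, `direction` (+1 / -1).
#' @export
filter_de <- function(table, fdr = 0.05, fold = 2) {
  stopifnot(inherits(table, "de_table"))
  if (!is_scalar_number(fold) || fold < 1) stopf("fold must be >= 1")
  if (!is_scalar_number(fdr) || fdr < 0 || fdr > 1) stopf("fdr must be in [0, 1]")
  keep <- table$padj <= fdr & abs(table$log2fc) >= log2(fold)
  out <- table[keep, c("gene_id", "log2fc", "padj"), drop = FALSE]
  out$direction <- as.integer(sign(out$log2fc))
  rownames(out) <- NULL
  class(out) <- c("de_gene_set", "data.frame")
  out
}

#' Direction-concordant intersection of two filtered gene sets
#'
#' Genes significant in both contrasts with the same sign of change, split
#' into jointly up- and jointly down-regulated.
#'
#' @param a,b `de_gene_set` objects from [filter_de()], with comparable
#'   gene identifiers.
#' @return A list of class `concordance_summary`: `n_a`, `n_b`,
#'   `n_concordant`, `n_up`, `n_down`, `genes_up`, `genes_down`.
#' @export
concordant_intersect <- function(a, b) {
  stopifnot(inherits(a, "de_gene_set"), inherits(b, "de_gene_set"))
  m <- merge(a[, c("gene_id", "direction")], b[, c("gene_id", "direction")],
             by = "gene_id", suffixes = c("_a", "_b"))
  conc <- m[m$direction_a == m$direction_b, ]
  up <- sort(conc$gene_id[conc$direction_a > 0])
  down <- sort(conc$gene_id[conc$direction_a < 0])
  structure(list(n_a = nrow(a), n_b = nrow(b),
                 n_concordant = length(up) + length(down),
                 n_up = length(up), n_down = length(down),
                 genes_up = up, genes_down = down),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "concordant DE: %d genes (%d up, %d down) of %d / %d filtered genes\n",
    x$n_concordant, x$n_up, x$n_down, x$n_a, x$n_b))
  invisible(x)
}
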