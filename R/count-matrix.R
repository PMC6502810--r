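#' Count matrix with sample roles
#'
#' Container for a transcripts-by-samples table of raw integer counts,
#' together with per-sample metadata. Each sample carries a `role`
#' (`"ip"`, `"control"`, `"bulk"`, or `"fraction:<label>"` for ribosome
#' fractions) and optionally a `genotype` (e.g. `"WT"` / `"KO"`).
#'
#' @param counts Integer matrix, transcripts in rows (rownames are
#'   transcript ids), samples in columns (colnames are sample ids).
#'   All entries must be non-negative integers.
#' @param samples Data frame with columns `sample_id`, `role` and
#'   optionally `genotype`; one row per column of `counts`, in order.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (the integer matrix) and `samples` (the metadata frame).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 8L, 1L, 2L), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("ip_1", "ctrl_1")))
#' cm <- count_matrix(m, data.frame(sample_id = colnames(m),
#'                                  role = c("ip", "control")))
#' dim(cm)
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("'counts' must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("'counts' must have transcript rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stopf("duplicate transcript_id: %s",
          rownames(counts)[duplicated(rownames(counts))][1])
  }
  if (anyDuplicated(colnames(counts))) {
    stopf("duplicate sample_id: %s",
          colnames(counts)[duplicated(colnames(counts))][1])
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != floor(counts),
                 arr.ind = TRUE)[1, ]
    stopf("counts must be non-negative integers; offending cell row '%s', column '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(samples))) {
    stopf("'samples' must have columns sample_id and role")
  }
  if (nrow(samples) != ncol(counts) ||
      !identical(as.character(samples$sample_id), colnames(counts))) {
    stopf("'samples$sample_id' must match colnames(counts) in order")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("roles:", paste(sprintf("%s=%s", x$samples$sample_id, x$samples$role),
                      collapse = ", "), "\n")
  invisible(x)
}

# columns of a count_matrix with a given role (and optional genotype)
samples_with_role <- function(cm, role, genotype = NULL) {
  keep <- cm$samples$role %in% role
  if (!is.null(genotype) && "genotype" %in% names(cm$samples)) {
    keep <- keep & cm$samples$genotype %in% genotype
  }
  cm$samples$sample_id[keep]
}

#' Read a count table from TSV
#'
#' Reads a tab-separated file whose first column is `transcript_id` and whose
#' remaining columns are integer counts (one per sample, named in the header),
#' and attaches sample roles.
#'
#' @param path Path to the TSV file.
#' @param role_map Named character vector mapping sample ids to roles
#'   (`"ip"`, `"control"`, `"bulk"`, `"fraction:<label>"`). Every sample in
#'   the file must be present.
#' @param genotype_map Optional named character vector mapping sample ids to
#'   genotype labels.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, role_map, genotype_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stopf("count table needs a transcript_id column plus >= 1 sample")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stopf("duplicate transcript_id '%s' in %s", ids[duplicated(ids)][1], path)
  }
  m <- matrix(NA_integer_, nrow = nrow(df), ncol = ncol(df) - 1,
              dimnames = list(ids, names(df)[-1]))
  for (j in seq_len(ncol(m))) {
    col <- names(df)[j + 1]
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stopf("non-integer or negative count at row '%s', column '%s'",
            ids[bad[1]], col)
    }
    m[, j] <- as.integer(v)
  }
  missing_roles <- setdiff(colnames(m), names(role_map))
  if (length(missing_roles)) {
    stopf("no role given for sample(s): %s", paste(missing_roles, collapse = ", "))
  }
  samples <- data.frame(sample_id = colnames(m),
                        role = unname(role_map[colnames(m)]),
                        stringsAsFactors = FALSE)
  if (!is.null(genotype_map)) {
    samples$genotype <- unname(genotype_map[colnames(m)])
  }
  count_matrix(m, samples)
}

#' Write a count table to TSV
#'
#' Inverse of [read_counts()]: writes the counts with a `transcript_id`
#' first column and one column per sample.
#'
#' @param cm A [count_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(transcript_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
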