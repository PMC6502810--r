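#' Normalization configuration for RIP-seq enrichment
#'
#' @param size_factor_method `"median_of_ratios"` (DESeq-style, default) or
#'   `"per_million"` (column sum / 1e6).
#' @param pseudocount Positive value added to both role means before the
#'   enrichment ratio (default 1, on the adjusted-FPKM scale).
#' @param detection_floor A transcript is called detected when its mean
#'   adjusted FPKM reaches this floor in either the IP or the control role
#'   (default 1). Non-negative.
#' @return A list of class `norm_config`.
#' @export
norm_config <- function(size_factor_method = c("median_of_ratios", "per_million"),
                        pseudocount = 1, detection_floor = 1) {
  size_factor_method <- match.arg(size_factor_method)
  if (!is_scalar_number(pseudocount) || pseudocount <= 0) {
    stopf("pseudocount must be > 0")
  }
  if (!is_scalar_number(detection_floor) || detection_floor < 0) {
    stopf("detection_floor must be >= 0")
  }
  structure(list(size_factor_method = size_factor_method,
                 pseudocount = pseudocount,
                 detection_floor = detection_floor),
            class = "norm_config")
}

#' Per-sample size factors
#'
#' `median_of_ratios` follows the DESeq definition: for each sample, the
#' median over transcripts (restricted to transcripts with nonzero counts in
#' every sample) of the ratio of the count to the transcript's geometric
#' mean across samples. `per_million` is the column sum divided by 1e6.
#'
#' @param counts A [count_matrix] or plain integer matrix.
#' @param method `"median_of_ratios"` or `"per_million"`.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts, method = c("median_of_ratios", "per_million")) {
  method <- match.arg(method)
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (all(m == 0)) stopf("all-zero count matrix: size factors undefined")
  if (method == "per_million") {
    sf <- colSums(m) / 1e6
    if (any(sf <= 0)) stopf("sample with zero total count: size factor undefined")
    return(sf)
  }
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) {
    stopf("median_of_ratios needs >= 1 transcript with nonzero counts in all samples")
  }
  lm <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lm)
  apply(lm, 2, function(col) exp(stats::median(col - geo)))
}

#' Size-factor-adjusted FPKM
#'
#' Computes, per cell,
#' `(count / size_factor) * 1e9 / (length_nt * effective_library_size)`,
#' where the effective library size is common to all samples: the geometric
#' mean over samples of `library_size / size_factor` (the robust convention
#' also used by DESeq2's `fpkm`). Dividing every sample by the same
#' effective depth means between-sample ratios depend only on the
#' size-factor-corrected counts and are immune to composition bias from
#' strongly enriched subsets.
#'
#' @param counts A [count_matrix] or integer matrix.
#' @param transcripts A [transcript_table] supplying `length_nt` for every
#'   row of `counts` (matched by transcript id).
#' @param factors Named per-sample size factors, as from [size_factors()].
#' @return Numeric matrix of adjusted FPKM, same dimnames as the counts.
#' @export
adjusted_fpkm <- function(counts, transcripts, factors) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  missing <- setdiff(rownames(m), transcripts$transcript_id)
  if (length(missing)) {
    stopf("no length available for transcript '%s'", missing[1])
  }
  len <- transcripts[rownames(m), "length_nt"]
  if (is.null(names(factors)) || !all(colnames(m) %in% names(factors))) {
    stopf("'factors' must be named for every sample")
  }
  f <- factors[colnames(m)]
  libsize <- colSums(m)
  if (any(libsize == 0)) stopf("sample with zero library size")
  eff_lib <- exp(mean(log(libsize / f)))
  adj <- sweep(m, 2, f, "/")
  out <- adj * 1e9 / (len * eff_lib)
  dimnames(out) <- dimnames(m)
  out
}

#' RIP-seq fold enrichment per transcript
#'
#' Averages adjusted FPKM over replicates within the IP and control roles
#' (arithmetic mean on the FPKM scale) and forms the pseudocounted ratio
#' `(mean_ip + pc) / (mean_control + pc)`. A transcript is `detected` when
#' either role mean reaches the detection floor; only detected transcripts
#' enter binder calling.
#'
#' @param ip_expr,control_expr Adjusted-FPKM matrices (transcripts x
#'   replicates) with identical rownames, as from [adjusted_fpkm()].
#' @param config A [norm_config].
#' @return Data frame of class `enrichment_result` with columns
#'   `transcript_id`, `mean_ip`, `mean_control`, `fold_enrichment`,
#'   `log2_ip`, `log2_control` (log2 of mean + 1), `detected`.
#' @export
rip_enrichment <- function(ip_expr, control_expr, config = norm_config()) {
  if (is.null(dim(ip_expr)) || ncol(ip_expr) < 1) stopf("empty IP role")
  if (is.null(dim(control_expr)) || ncol(control_expr) < 1) stopf("empty control role")
  if (!identical(rownames(ip_expr), rownames(control_expr))) {
    stopf("IP and control matrices must share the same transcript universe")
  }
  pc <- config$pseudocount
  mi <- rowMeans(ip_expr)
  mc <- rowMeans(control_expr)
  out <- data.frame(
    transcript_id = rownames(ip_expr),
    mean_ip = mi,
    mean_control = mc,
    fold_enrichment = (mi + pc) / (mc + pc),
    log2_ip = log2(mi + 1),
    log2_control = log2(mc + 1),
    detected = mi >= config$detection_floor | mc >= config$detection_floor,
    row.names = rownames(ip_expr),
    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Binder set
#'
#' The set of transcripts called bound at a fold-enrichment cutoff, with the
#' size of the detected universe they were drawn from. Can also be built
#' directly from ids, e.g. to work with published binder counts.
#'
#' @param members Character vector of transcript ids.
#' @param universe_size Number of detected transcripts the set was drawn
#'   from (positive integer, `>= length(members)`).
#' @param cutoff Fold-enrichment cutoff used (or `NA` for externally
#'   defined sets).
#' @return A list of class `binder_set` with elements `members`,
#'   `universe_size`, `cutoff`.
#' @export
binder_set <- function(members, universe_size, cutoff = NA_real_) {
  members <- unique(as.character(members))
  if (!is_count(universe_size) || universe_size < 1) {
    stopf("universe_size must be a positive integer")
  }
  if (length(members) > universe_size) {
    stopf("binder set larger than its universe")
  }
  structure(list(members = members,
                 universe_size = as.integer(universe_size),
                 cutoff = cutoff),
            class = "binder_set")
}

#' @export
print.binder_set <- function(x, ...) {
  cat(sprintf("binder_set: %d transcripts (universe %d%s)\n",
              length(x$members), x$universe_size,
              if (is.na(x$cutoff)) "" else sprintf(", fold cutoff > %g", x$cutoff)))
  invisible(x)
}

#' @export
length.binder_set <- function(x) length(x$members)

#' Call bound transcripts at a fold-enrichment cutoff
#'
#' Members are the detected transcripts whose fold enrichment is strictly
#' greater than the cutoff ("more than `cutoff`-fold"). The universe is the
#' set of detected transcripts.
#'
#' @param results An `enrichment_result` from [rip_enrichment()].
#' @param cutoff Positive fold-enrichment cutoff (default 4).
#' @return A [binder_set].
#' @export
call_binders <- function(results, cutoff = 4) {
  stopifnot(inherits(results, "enrichment_result"))
  if (nrow(results) == 0) stopf("empty enrichment results")
  if (!is_scalar_number(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  det <- results[results$detected, , drop = FALSE]
  binder_set(det$transcript_id[det$fold_enrichment > cutoff],
             universe_size = max(nrow(det), 1L),
             cutoff = cutoff)
}
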