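#' Ribosome fraction scheme
#'
#' Ordered fraction labels with their class assignment: `free` (mRNPs not
#' ribosome-engaged), `mono` (80S monosome), `poly` (polyribosome
#' fractions, pooled downstream by summation).
#'
#' @param labels Character vector of unique fraction labels, in gradient
#'   order.
#' @param classes Character vector of the same length over
#'   `{"free", "mono", "poly"}`; each class must appear at least once.
#' @return A list of class `fraction_scheme` with `labels` and `classes`.
#' @export
fraction_scheme <- function(labels, classes) {
  labels <- as.character(labels)
  classes <- as.character(classes)
  if (length(labels) != length(classes)) stopf("labels and classes differ in length")
  if (anyDuplicated(labels)) stopf("fraction labels must be unique")
  if (!all(classes %in% c("free", "mono", "poly"))) {
    stopf("classes must be one of free, mono, poly")
  }
  if (!all(c("free", "mono", "poly") %in% classes)) {
    stopf("each class (free, mono, poly) needs at least one fraction")
  }
  structure(list(labels = labels, classes = stats::setNames(classes, labels)),
            class = "fraction_scheme")
}

#' Default five-fraction scheme
#'
#' One free-mRNA fraction, one 80S monosome fraction, and three pooled
#' polysome fractions — the coarsest scheme that distinguishes initiation
#' (free vs engaged) from elongation (mono vs poly) states.
#'
#' @return A [fraction_scheme].
#' @export
default_fraction_scheme <- function() {
  fraction_scheme(c("free", "mono", "poly1", "poly2", "poly3"),
                  c("free", "mono", "poly", "poly", "poly"))
}

fraction_label <- function(role) sub("^fraction:", "", role)

# median-of-ratios factors restricted to a reference row subset
mor_factors <- function(m, rows) {
  keep <- rows & rowSums(m > 0) == ncol(m)
  if (sum(keep) < 2) keep <- rowSums(m > 0) == ncol(m)  # degenerate reference
  if (sum(keep) == 0) {
    stopf("size factors need >= 1 transcript with nonzero counts in all samples")
  }
  lm_ <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lm_)
  apply(lm_, 2, function(col) exp(stats::median(col - geo)))
}

# iterated size factors anchored on the translationally stable majority:
# transcripts whose between-genotype poly/free ratio sits within 2-fold of
# the mode of the log-ratio distribution
stable_reference_factors <- function(cm, scheme, genotypes, max_iter = 5) {
  m <- cm$counts
  rows <- rep(TRUE, nrow(m))
  sf <- mor_factors(m, rows)
  gts <- unique(genotypes)
  if (length(gts) != 2 || nrow(m) < 20) return(sf)
  labs <- fraction_label(cm$samples$role)
  cls <- scheme$classes[labs]
  pooled <- function(sf, gt, which_class) {
    cols <- cm$samples$sample_id[genotypes == gt & cls == which_class]
    norm <- sweep(m[, cols, drop = FALSE], 2, sf[cols], "/")
    reps <- table(labs[genotypes == gt & cls == which_class])
    rowSums(norm) / mean(reps)  # replicate-mean per fraction, summed over class
  }
  for (i in seq_len(max_iter)) {
    te1 <- pooled(sf, gts[1], "poly") / pooled(sf, gts[1], "free")
    te2 <- pooled(sf, gts[2], "poly") / pooled(sf, gts[2], "free")
    lr <- log(te2 / te1)
    ok <- is.finite(lr)
    if (sum(ok) < 10) break
    d <- stats::density(lr[ok])
    ctr <- d$x[which.max(d$y)]
    new_rows <- ok & abs(lr - ctr) < log(2)
    if (identical(new_rows, rows)) break
    rows <- new_rows
    sf <- mor_factors(m, rows)
  }
  sf
}

#' Per-transcript fraction profiles
#'
#' Normalizes fraction-resolved counts (each fraction sample is its own
#' library: per-sample size factors), averages replicates within each
#' fraction and genotype, and expresses each transcript's abundance as a
#' percentage of its own total across fractions.
#'
#' The default `"stable_reference"` method guards against a bias specific
#' to fraction libraries: when a sizeable minority of transcripts moves
#' coherently between fractions in one genotype (here, up to ~30% of mRNAs
#' losing ribosome-engaged mass), plain median-of-ratios factors are pulled
#' toward the shifted transcripts and compress the between-genotype ratios.
#' The method starts from median-of-ratios factors and iterates: it pools
#' class abundances, forms each transcript's between-genotype poly/free
#' ratio, locates the mode of the log-ratio distribution (the
#' translationally stable majority), and recomputes median-of-ratios
#' factors on the transcripts within 2-fold of that mode. With a single
#' genotype it reduces to plain median-of-ratios.
#'
#' @param counts A [count_matrix] whose samples all have role
#'   `"fraction:<label>"` with labels from `scheme`, plus a `genotype`
#'   column.
#' @param scheme A [fraction_scheme].
#' @param method `"stable_reference"` (default), `"median_of_ratios"` or
#'   `"per_million"`.
#' @param max_iter Maximum refinement iterations for `"stable_reference"`
#'   (default 5; typically converges in 2).
#' @return Long data frame of class `fraction_profiles` with columns
#'   `transcript_id`, `genotype`, `fraction`, `abundance`, `pct`
#'   (`NA` when the transcript total is zero); the scheme is attached as
#'   attribute `"scheme"`.
#' @export
normalize_fractions <- function(counts, scheme = default_fraction_scheme(),
                                method = c("stable_reference",
                                           "median_of_ratios", "per_million"),
                                max_iter = 5) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "count_matrix"), inherits(scheme, "fraction_scheme"))
  roles <- counts$samples$role
  if (!all(grepl("^fraction:", roles))) {
    stopf("every sample must have a 'fraction:<label>' role")
  }
  labs <- fraction_label(roles)
  unknown <- setdiff(labs, scheme$labels)
  if (length(unknown)) {
    stopf("fraction '%s' present in data but absent from scheme", unknown[1])
  }
  genotypes <- if ("genotype" %in% names(counts$samples)) {
    counts$samples$genotype
  } else {
    rep("WT", nrow(counts$samples))
  }
  sf <- if (method == "per_million") {
    size_factors(counts, "per_million")
  } else if (method == "median_of_ratios") {
    size_factors(counts, "median_of_ratios")
  } else {
    stable_reference_factors(counts, scheme, genotypes, max_iter)
  }
  norm <- sweep(counts$counts, 2, sf, "/")
  out <- list()
  for (g in unique(genotypes)) {
    ab <- vapply(scheme$labels, function(lab) {
      cols <- counts$samples$sample_id[labs == lab & genotypes == g]
      if (length(cols) == 0) stopf("genotype %s has no sample for fraction '%s'", g, lab)
      rowMeans(norm[, cols, drop = FALSE])
    }, numeric(nrow(norm)))
    ab <- matrix(ab, nrow = nrow(norm),
                 dimnames = list(rownames(norm), scheme$labels))
    total <- rowSums(ab)
    pct <- 100 * ab / total  # NaN rows (total 0) -> NA below
    pct[total == 0, ] <- NA_real_
    out[[g]] <- data.frame(
      transcript_id = rep(rownames(ab), times = ncol(ab)),
      genotype = g,
      fraction = rep(colnames(ab), each = nrow(ab)),
      abundance = as.vector(ab),
      pct = as.vector(pct),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$fraction <- factor(res$fraction, levels = scheme$labels)
  attr(res, "scheme") <- scheme
  class(res) <- c("fraction_profiles", "data.frame")
  res
}

#' Pooled translation-state ratios
#'
#' For each transcript and genotype, pools fraction abundances by class and
#' forms the translation-efficiency ratio `te = poly / free` and the
#' elongation ratio `poly_mono = poly / mono`. A pseudo-term of
#' `eps_frac` times the transcript's total abundance is added to each
#' denominator; transcripts with zero total are flagged undefined and
#' excluded downstream.
#'
#' @param profiles A `fraction_profiles` from [normalize_fractions()].
#' @param scheme A [fraction_scheme] (default: the one attached to
#'   `profiles`).
#' @param eps_frac Denominator pseudo-term as a fraction of the transcript
#'   total (default `1e-6`).
#' @return Data frame of class `pooled_ratios` with columns
#'   `transcript_id`, `genotype`, `free`, `mono`, `poly`, `te`,
#'   `poly_mono`, `defined`.
#' @export
pooled_ratios <- function(profiles, scheme = attr(profiles, "scheme"),
                          eps_frac = 1e-6) {
  stopifnot(inherits(profiles, "fraction_profiles"), inherits(scheme, "fraction_scheme"))
  cls <- scheme$classes[as.character(profiles$fraction)]
  key <- interaction(profiles$transcript_id, profiles$genotype, drop = TRUE)
  pool <- function(which_class) {
    v <- profiles$abundance
    v[cls != which_class] <- 0
    tapply(v, key, sum)
  }
  free <- pool("free"); mono <- pool("mono"); poly <- pool("poly")
  ids <- tapply(profiles$transcript_id, key, `[`, 1)
  gts <- tapply(profiles$genotype, key, `[`, 1)
  total <- free + mono + poly
  eps <- eps_frac * total
  te <- ifelse(total > 0, poly / (free + eps), NA_real_)
  pm <- ifelse(total > 0, poly / (mono + eps), NA_real_)
  out <- data.frame(transcript_id = as.character(ids),
                    genotype = as.character(gts),
                    free = as.numeric(free),
                    mono = as.numeric(mono),
                    poly = as.numeric(poly),
                    te = as.numeric(te),
                    poly_mono = as.numeric(pm),
                    defined = as.numeric(total) > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pooled_ratios", "data.frame")
  out
}

#' Classify translation-initiation shifts between genotypes
#'
#' A transcript falls in group 1 (decreased translation initiation) when
#' its knockout poly/free ratio drops strictly below `threshold` times the
#' wild-type ratio ("decreased by more than half" at the default 0.5);
#' everything else is group 2. Transcripts with an undefined ratio in
#' either genotype get `group = NA` with a reason code.
#'
#' @param ratios A `pooled_ratios` containing both genotypes.
#' @param wt,ko Genotype labels (defaults `"WT"`, `"KO"`).
#' @param threshold Strict ratio threshold in `(0, 1]` (default 0.5).
#' @return Data frame of class `shift_calls`: `transcript_id`, `te_wt`,
#'   `te_ko`, `poly_mono_wt`, `poly_mono_ko`, `group` (1, 2 or `NA`),
#'   `reason`.
#' @export
classify_shift <- function(ratios, wt = "WT", ko = "KO", threshold = 0.5) {
  stopifnot(inherits(ratios, "pooled_ratios"))
  if (!is_scalar_number(threshold) || threshold <= 0) {
    stopf("threshold must be > 0")
  }
  a <- ratios[ratios$genotype == wt, ]
  b <- ratios[ratios$genotype == ko, ]
  if (nrow(a) == 0 || nrow(b) == 0) stopf("both genotypes must be present")
  m <- merge(a, b, by = "transcript_id", suffixes = c("_wt", "_ko"))
  ok <- m$defined_wt & m$defined_ko
  group <- ifelse(ok, ifelse(m$te_ko < threshold * m$te_wt, 1L, 2L), NA_integer_)
  out <- data.frame(transcript_id = m$transcript_id,
                    te_wt = m$te_wt, te_ko = m$te_ko,
                    poly_mono_wt = m$poly_mono_wt,
                    poly_mono_ko = m$poly_mono_ko,
                    group = as.integer(group),
                    reason = ifelse(ok, NA_character_, "undefined_te"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("shift_calls", "data.frame")
  out
}

#' Enrichment of translation shifts in a bound set
#'
#' Tests whether protein-bound transcripts are over-represented among
#' group-1 (initiation-impaired) transcripts. The global group-1 proportion
#' over all classified transcripts is the expected proportion; a one-sample
#' goodness-of-fit chi-square is applied to the group-1 count among the
#' bound subset.
#'
#' @param calls A `shift_calls` from [classify_shift()].
#' @param bound A [binder_set] (or character vector of transcript ids);
#'   only bound transcripts with a defined call are tested.
#' @return A list of class `shift_enrichment`: `test` (a `chisq_gof`),
#'   `n_classified`, `n_bound`, `k_bound_group1`,
#'   `pct_global_group1`, `pct_bound_group1`.
#' @export
shift_enrichment <- function(calls, bound) {
  stopifnot(inherits(calls, "shift_calls"))
  ids <- if (inherits(bound, "binder_set")) bound$members else as.character(bound)
  ok <- calls[!is.na(calls$group), ]
  if (nrow(ok) == 0) stopf("no classified transcripts")
  p_global <- mean(ok$group == 1L)
  sub <- ok[ok$transcript_id %in% ids, ]
  n <- nrow(sub)
  if (n == 0) stopf("no bound transcript has a defined shift call")
  k <- sum(sub$group == 1L)
  test <- goodness_of_fit_chisq(k, n, p_global)
  structure(list(test = test,
                 n_classified = nrow(ok),
                 n_bound = n,
                 k_bound_group1 = k,
                 pct_global_group1 = round_half_up(100 * p_global),
                 pct_bound_group1 = round_half_up(100 * k / n)),
            class = "shift_enrichment")
}

#' @export
print.shift_enrichment <- function(x, ...) {
  cat(sprintf(
    "shift enrichment: group 1 = %d%% of bound (n=%d) vs %d%% global (n=%d); X2 = %.4g, p = %.3g\n",
    x$pct_bound_group1, x$n_bound, x$pct_global_group1, x$n_classified,
    x$test$statistic, x$test$p_value))
  invisible(x)
}
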