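#' Pipeline run configuration
#'
#' Bundles the analysis thresholds (fold-enrichment cutoff, shift-ratio
#' threshold, DE filters) with a simulation config for demo runs.
#'
#' @param seed Integer seed, propagated to the simulation config.
#' @param cutoff Fold-enrichment binder cutoff (default 4).
#' @param shift_threshold Translation-shift ratio threshold (default 0.5).
#' @param fdr,fold DE filter thresholds (defaults 0.05 and 2).
#' @param sim A [sim_config]; defaults to `sim_config(seed = seed)`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, cutoff = 4, shift_threshold = 0.5,
                       fdr = 0.05, fold = 2, sim = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  stopifnot(inherits(sim, "sim_config"))
  if (cutoff <= 0) stopf("cutoff must be > 0")
  if (shift_threshold <= 0) stopf("shift_threshold must be > 0")
  if (fold < 1) stopf("fold must be >= 1")
  structure(list(seed = as.integer(seed), cutoff = cutoff,
                 shift_threshold = shift_threshold, fdr = fdr, fold = fold,
                 sim = sim),
            class = "run_config")
}

#' Run the full synthetic demo pipeline
#'
#' Chains all stages on generated data: RIP-seq simulation, normalization
#' and binder calling; CLIP peak simulation and transcript coverage;
#' polysome-fraction simulation, shift classification and bound-set
#' enrichment; DE simulation and direction-concordant intersection.
#' Deterministic given the config's seed.
#'
#' @param config A [run_config].
#' @param out_json Optional path; when given, the report is also written as
#'   JSON.
#' @return A list of class `pipeline_report` with one element per stage
#'   plus the echoed configuration.
#' @export
run_pipeline <- function(config = run_config(), out_json = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim

  rip <- simulate_ripseq(sim)
  sf <- size_factors(rip$counts, "median_of_ratios")
  fpkm <- adjusted_fpkm(rip$counts, rip$transcripts, sf)
  ip_cols <- samples_with_role(rip$counts, "ip")
  ctrl_cols <- samples_with_role(rip$counts, "control")
  enr <- rip_enrichment(fpkm[, ip_cols, drop = FALSE],
                        fpkm[, ctrl_cols, drop = FALSE])
  binders <- call_binders(enr, cutoff = config$cutoff)
  sens <- length(intersect(binders$members, rip$truth_bound)) /
    length(rip$truth_bound)
  fdr_obs <- if (length(binders$members) > 0) {
    length(setdiff(binders$members, rip$truth_bound)) / length(binders$members)
  } else 0

  peaks <- simulate_eclip(sim, rip$transcripts, rip$truth_bound)
  coverage <- if (length(binders$members) > 0 && length(peaks) > 0) {
    clip_coverage(binders, peaks, rip$transcripts)
  } else NULL

  poly <- simulate_polysome(sim, rip$truth_bound)
  profiles <- normalize_fractions(poly$counts, sim$scheme)
  ratios <- pooled_ratios(profiles)
  calls <- classify_shift(ratios, threshold = config$shift_threshold)
  shift <- if (length(binders$members) > 0) {
    shift_enrichment(calls, binders)
  } else NULL

  de <- simulate_de(sim)
  conc <- concordant_intersect(filter_de(de$a, config$fdr, config$fold),
                               filter_de(de$b, config$fdr, config$fold))

  report <- structure(list(
    config = list(seed = config$seed, cutoff = config$cutoff,
                  shift_threshold = config$shift_threshold,
                  fdr = config$fdr, fold = config$fold,
                  n_transcripts = sim$n_transcripts, n_bound = sim$n_bound,
                  bound_fold = sim$bound_fold,
                  shift_fraction = sim$shift_fraction,
                  shift_strength = sim$shift_strength),
    ripseq = list(n_detected = binders$universe_size,
                  n_binders = length(binders$members),
                  transcriptome_pct = transcriptome_fraction(binders),
                  sensitivity = sens, fdr_observed = fdr_obs,
                  size_factors = as.list(sf)),
    clip = if (is.null(coverage)) NULL else list(
      n_peaks = length(peaks),
      n_queried = coverage$n_queried,
      n_covered = coverage$n_covered,
      pct_covered = coverage$pct_covered),
    polysome = if (is.null(shift)) NULL else list(
      n_classified = shift$n_classified,
      pct_global_group1 = shift$pct_global_group1,
      n_bound = shift$n_bound,
      pct_bound_group1 = shift$pct_bound_group1,
      chisq_statistic = shift$test$statistic,
      chisq_p = shift$test$p_value),
    concordance = list(n_a = conc$n_a, n_b = conc$n_b,
                       n_concordant = conc$n_concordant,
                       n_up = conc$n_up, n_down = conc$n_down)),
    class = "pipeline_report")

  if (!is.null(out_json)) {
    jsonlite::write_json(unclass(report), out_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== synthetic pipeline report (seed", x$config$seed, ") ==\n")
  cat(sprintf("RIP-seq: %d binders (fold > %g) of %d detected (%d%% of transcriptome); sensitivity %.3f, observed FDR %.3f\n",
              x$ripseq$n_binders, x$config$cutoff, x$ripseq$n_detected,
              x$ripseq$transcriptome_pct, x$ripseq$sensitivity,
              x$ripseq$fdr_observed))
  if (!is.null(x$clip)) {
    cat(sprintf("CLIP: %d / %d binders covered by >= 1 peak (%d%%), %d peaks\n",
                x$clip$n_covered, x$clip$n_queried, x$clip$pct_covered,
                x$clip$n_peaks))
  }
  if (!is.null(x$polysome)) {
    cat(sprintf("Polysome: group 1 = %d%% globally (n=%d), %d%% among binders (n=%d); X2 = %.4g, p = %.3g\n",
                x$polysome$pct_global_group1, x$polysome$n_classified,
                x$polysome$pct_bound_group1, x$polysome$n_bound,
                x$polysome$chisq_statistic, x$polysome$chisq_p))
  }
  cat(sprintf("Concordant DE: %d genes (%d up, %d down) from %d / %d filtered\n",
              x$concordance$n_concordant, x$concordance$n_up,
              x$concordance$n_down, x$concordance$n_a, x$concordance$n_b))
  invisible(x)
}
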