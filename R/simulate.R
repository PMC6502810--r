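#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Counts follow a negative
#' binomial with lognormal baseline means (standard bulk RNA-seq emulation);
#' planted effects mirror the structures the analysis stages assume: an
#' IP-enriched bound subset, a translation-initiation block that moves
#' ribosome-engaged mass to the free fraction while preserving poly:mono
#' proportions among the still-engaged mass, CLIP peaks concentrated on
#' bound transcripts, and a direction-concordant differentially expressed
#' subset.
#'
#' @param seed Integer seed; every generator is a pure function of its
#'   config (keep below 2^31 - 16).
#' @param n_transcripts Number of transcripts (default 2000).
#' @param n_bound Number of planted bound transcripts (default 100).
#' @param bound_fold IP fold enrichment of bound transcripts (default 8).
#' @param nb_dispersion Negative-binomial dispersion (default 0.1).
#' @param n_replicates Replicates per role / per fraction (default 3).
#' @param scheme Ribosome [fraction_scheme] (default
#'   [default_fraction_scheme()]).
#' @param shift_fraction Share of transcripts given an initiation block
#'   (default 0.3).
#' @param shift_strength Share of ribosome-engaged (mono + poly) mass moved
#'   to the free fraction in the knockout, in `(0, 1]`; 0 disables the
#'   effect (default 0.75).
#' @param binder_shift_multiplier Relative propensity of bound transcripts
#'   to be shifted, `>= 1` (default 3).
#' @param de_concordant Planted concordant DE genes, `c(up, down)`
#'   (default `c(138, 74)`).
#' @param peak_rate_bound,peak_rate_unbound Mean CLIP peaks per transcript
#'   (defaults 2 and 0.2).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of baseline
#'   expression means in counts (defaults `log(200)` and 1).
#' @param dirichlet_concentration Concentration of per-transcript fraction
#'   proportions around the class means; larger is tighter (default 150).
#' @param depth_sdlog Lognormal sd of per-sample sequencing-depth factors
#'   (default 0.2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 2000L,
                       n_bound = 100L,
                       bound_fold = 8,
                       nb_dispersion = 0.1,
                       n_replicates = 3L,
                       scheme = default_fraction_scheme(),
                       shift_fraction = 0.3,
                       shift_strength = 0.75,
                       binder_shift_multiplier = 3,
                       de_concordant = c(up = 138L, down = 74L),
                       peak_rate_bound = 2,
                       peak_rate_unbound = 0.2,
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1,
                       dirichlet_concentration = 150,
                       depth_sdlog = 0.2) {
  if (!is_count(seed)) stopf("seed must be a non-negative integer")
  if (!is_count(n_transcripts) || n_transcripts < 1) stopf("n_transcripts must be >= 1")
  if (!is_count(n_bound) || n_bound > n_transcripts) {
    stopf("n_bound must be an integer <= n_transcripts")
  }
  if (bound_fold <= 0 || nb_dispersion <= 0) stopf("rates must be positive")
  if (shift_fraction < 0 || shift_fraction > 1) stopf("shift_fraction in [0, 1]")
  if (shift_strength < 0 || shift_strength > 1) stopf("shift_strength in [0, 1]")
  if (binder_shift_multiplier < 1) stopf("binder_shift_multiplier must be >= 1")
  if (peak_rate_bound < 0 || peak_rate_unbound < 0) stopf("peak rates must be >= 0")
  stopifnot(inherits(scheme, "fraction_scheme"))
  structure(list(seed = as.integer(seed),
                 n_transcripts = as.integer(n_transcripts),
                 n_bound = as.integer(n_bound),
                 bound_fold = bound_fold,
                 nb_dispersion = nb_dispersion,
                 n_replicates = as.integer(n_replicates),
                 scheme = scheme,
                 shift_fraction = shift_fraction,
                 shift_strength = shift_strength,
                 binder_shift_multiplier = binder_shift_multiplier,
                 de_concordant = de_concordant,
                 peak_rate_bound = peak_rate_bound,
                 peak_rate_unbound = peak_rate_unbound,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dirichlet_concentration = dirichlet_concentration,
                 depth_sdlog = depth_sdlog),
            class = "sim_config")
}

sim_ids <- function(n) sprintf("tx%05d", seq_len(n))
sim_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# random transcript models laid out sequentially along four chromosomes
sim_transcripts <- function(n) {
  lens <- sample(500:5000, n, replace = TRUE)
  chrom <- paste0("chr", 1 + (seq_len(n) - 1) %% 4)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cursor <- stats::setNames(rep(10000L, 4), paste0("chr", 1:4))
  span_start <- integer(n); span_end <- integer(n)
  exon_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(1:3, 1)
    # composition of the transcript length into k exon widths (each >= 50)
    w <- if (k == 1) lens[i] else {
      cuts <- sort(sample(seq(50L, lens[i] - 50L * (k - 1), by = 1L), k - 1))
      diff(c(0L, cuts, lens[i]))
    }
    introns <- if (k > 1) sample(200:2000, k - 1, replace = TRUE) else integer(0)
    starts <- cursor[chrom[i]] + c(0L, cumsum(w[-k] + introns))
    ex <- cbind(start = as.integer(starts), end = as.integer(starts + w))
    exon_list[[i]] <- ex
    span_start[i] <- ex[1, 1]
    span_end[i] <- ex[k, 2]
    cursor[chrom[i]] <- span_end[i] + 1000L
  }
  transcript_table(sim_ids(n), sim_gene_ids(n), chrom, strand,
                   span_start, span_end, exons = exon_list)
}

#' Simulate RIP-seq counts with a planted bound subset
#'
#' Baseline per-transcript means are lognormal; counts are negative binomial
#' with the configured dispersion, scaled by per-sample depth factors. IP
#' samples multiply the means of `n_bound` randomly chosen transcripts by
#' `bound_fold`; control samples are untouched. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config].
#' @return List with `counts` (a [count_matrix] with `ip` / `control`
#'   roles), `transcripts` (a [transcript_table]) and `truth_bound`
#'   (character vector of planted bound transcript ids).
#' @export
simulate_ripseq <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  tt <- sim_transcripts(n)
  ids <- tt$transcript_id
  truth <- sort(sample(ids, config$n_bound))
  base_mu <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  r <- config$n_replicates
  sample_ids <- c(sprintf("ip_%d", seq_len(r)), sprintf("control_%d", seq_len(r)))
  roles <- rep(c("ip", "control"), each = r)
  depth <- stats::rlnorm(2 * r, 0, config$depth_sdlog)
  mu <- outer(base_mu, depth)
  mu[ids %in% truth, roles == "ip"] <- mu[ids %in% truth, roles == "ip"] * config$bound_fold
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow = n, dimnames = list(ids, sample_ids))
  cm <- count_matrix(counts, data.frame(sample_id = sample_ids, role = roles,
                                        stringsAsFactors = FALSE))
  list(counts = cm, transcripts = tt, truth_bound = truth)
}

# one Dirichlet draw per row of a base-proportion matrix
rdirichlet_rows <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  g / rowSums(g)
}

#' Simulate fraction-resolved polysome-profiling counts
#'
#' Each transcript's wild-type mass is spread across the scheme's fractions
#' by a Dirichlet draw around class means (free 20%, monosome 20%, polysome
#' 60% split evenly). In the knockout, planted shifted transcripts move
#' `shift_strength` of their ribosome-engaged (mono + poly) mass to the
#' free fraction, leaving the mono:poly proportions among the remaining
#' engaged mass unchanged — the signature of a translation-initiation block
#' rather than an elongation defect. Bound transcripts (if supplied) are
#' `binder_shift_multiplier` times as likely to be shifted.
#'
#' @param config A [sim_config].
#' @param truth_bound Character vector of bound transcript ids, e.g. from
#'   [simulate_ripseq()]; `NULL` for no binding/shift association.
#' @return List with `counts` (a [count_matrix] with `fraction:<label>`
#'   roles and a `genotype` column, WT and KO) and `truth_shifted`
#'   (character vector of planted shifted transcript ids).
#' @export
simulate_polysome <- function(config = sim_config(), truth_bound = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_transcripts
  ids <- sim_ids(n)
  scheme <- config$scheme
  labs <- scheme$labels
  cls <- scheme$classes
  # class means: free 0.2, mono 0.2, poly 0.6 split evenly
  base_p <- stats::setNames(numeric(length(labs)), labs)
  base_p[cls == "free"] <- 0.2 / sum(cls == "free")
  base_p[cls == "mono"] <- 0.2 / sum(cls == "mono")
  base_p[cls == "poly"] <- 0.6 / sum(cls == "poly")

  n_shift <- round(config$shift_fraction * n)
  w <- rep(1, n)
  if (!is.null(truth_bound)) w[ids %in% truth_bound] <- config$binder_shift_multiplier
  truth_shift <- if (n_shift > 0) sort(sample(ids, n_shift, prob = w)) else character(0)

  alpha <- matrix(config$dirichlet_concentration * base_p, nrow = n,
                  ncol = length(labs), byrow = TRUE)
  p_wt <- rdirichlet_rows(alpha)
  colnames(p_wt) <- labs
  p_ko <- p_wt
  s <- config$shift_strength
  shifted <- ids %in% truth_shift
  if (s > 0 && any(shifted)) {
    engaged_cols <- labs[cls != "free"]
    free_cols <- labs[cls == "free"]
    engaged <- rowSums(p_wt[shifted, engaged_cols, drop = FALSE])
    p_ko[shifted, engaged_cols] <- p_wt[shifted, engaged_cols, drop = FALSE] * (1 - s)
    # moved mass lands in the free class, split by its within-class proportions
    free_share <- p_wt[shifted, free_cols, drop = FALSE]
    free_share <- free_share / rowSums(free_share)
    p_ko[shifted, free_cols] <- p_wt[shifted, free_cols, drop = FALSE] +
      free_share * s * engaged
  }

  total_mu <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  r <- config$n_replicates
  grid <- expand.grid(rep = seq_len(r), fraction = labs,
                      genotype = c("WT", "KO"), stringsAsFactors = FALSE)
  sample_ids <- sprintf("%s_%s_%d", grid$genotype, grid$fraction, grid$rep)
  depth <- stats::rlnorm(nrow(grid), 0, config$depth_sdlog)
  counts <- matrix(0L, nrow = n, ncol = nrow(grid),
                   dimnames = list(ids, sample_ids))
  for (j in seq_len(nrow(grid))) {
    p <- if (grid$genotype[j] == "WT") p_wt else p_ko
    mu <- total_mu * p[, grid$fraction[j]] * depth[j]
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  }
  cm <- count_matrix(counts, data.frame(
    sample_id = sample_ids,
    role = paste0("fraction:", grid$fraction),
    genotype = grid$genotype,
    stringsAsFactors = FALSE))
  list(counts = cm, truth_shifted = truth_shift)
}

#' Simulate a pair of DE tables with a planted concordant subset
#'
#' Two knockout-vs-wild-type contrasts over the same genes. Planted
#' concordant genes pass the FDR and fold filters in both tables with
#' matching signs; decoy genes fail the FDR filter, fail the fold filter,
#' change in opposite directions, or are significant in only one contrast.
#'
#' @param config A [sim_config]; `de_concordant = c(up, down)` sets the
#'   planted counts.
#' @return List with `a` and `b` (two `de_table`s), `truth_up` and
#'   `truth_down` (planted concordant gene ids).
#' @export
simulate_de <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_transcripts
  ids <- sim_gene_ids(n)
  n_up <- as.integer(config$de_concordant[1])
  n_down <- as.integer(config$de_concordant[2])
  if (n_up + n_down > n) stopf("planted concordant genes exceed gene universe")
  planted <- sample(ids, n_up + n_down)
  up <- sort(planted[seq_len(n_up)])
  down <- sort(setdiff(planted, up))

  lfc_a <- stats::rnorm(n, 0, 0.3)
  lfc_b <- stats::rnorm(n, 0, 0.3)
  padj_a <- stats::runif(n, 0.2, 1)
  padj_b <- stats::runif(n, 0.2, 1)
  sig <- function(k) 10^stats::runif(k, -8, -2)    # always <= 0.05
  big <- function(k) stats::runif(k, 1.2, 3)       # always >= log2(2)

  i_up <- match(up, ids); i_down <- match(down, ids)
  lfc_a[i_up] <- big(n_up);    lfc_b[i_up] <- big(n_up)
  lfc_a[i_down] <- -big(n_down); lfc_b[i_down] <- -big(n_down)
  padj_a[c(i_up, i_down)] <- sig(n_up + n_down)
  padj_b[c(i_up, i_down)] <- sig(n_up + n_down)

  decoys <- setdiff(ids, planted)
  type <- sample(c("null", "lowfold", "discordant", "onesided"),
                 length(decoys), replace = TRUE,
                 prob = c(0.55, 0.2, 0.1, 0.15))
  i <- match(decoys[type == "lowfold"], ids)
  padj_a[i] <- sig(length(i)); padj_b[i] <- sig(length(i))
  lfc_a[i] <- stats::runif(length(i), -0.9, 0.9)
  lfc_b[i] <- stats::runif(length(i), -0.9, 0.9)
  i <- match(decoys[type == "discordant"], ids)
  sgn <- sample(c(-1, 1), length(i), replace = TRUE)
  padj_a[i] <- sig(length(i)); padj_b[i] <- sig(length(i))
  lfc_a[i] <- sgn * big(length(i))
  lfc_b[i] <- -sgn * big(length(i))
  i <- match(decoys[type == "onesided"], ids)
  padj_a[i] <- sig(length(i))
  lfc_a[i] <- sample(c(-1, 1), length(i), replace = TRUE) * big(length(i))

  mk <- function(lfc, padj) {
    as_de_table(data.frame(gene_id = ids, log2fc = lfc, padj = padj,
                           stringsAsFactors = FALSE))
  }
  list(a = mk(lfc_a, padj_a), b = mk(lfc_b, padj_b),
       truth_up = up, truth_down = down)
}

#' Simulate CLIP peaks concentrated on bound transcripts
#'
#' Poisson peak counts per transcript at `peak_rate_bound` for bound
#' transcripts and `peak_rate_unbound` otherwise. Peaks (30-80 bp) are
#' placed within the transcript span, biased (80% of peaks) toward the
#' strand-aware 3'-terminal 30% of the span, matching the 3'-UTR location
#' typical of poly-C-binding-protein sites.
#'
#' @param config A [sim_config].
#' @param transcripts A [transcript_table], e.g. from [simulate_ripseq()].
#' @param truth_bound Character vector of bound transcript ids.
#' @return A `GRanges` of peaks with `name` and `score` metadata, strand
#'   matching the owning transcript.
#' @export
simulate_eclip <- function(config, transcripts, truth_bound) {
  stopifnot(inherits(config, "sim_config"), inherits(transcripts, "transcript_table"))
  set.seed(config$seed + 3L)
  n <- nrow(transcripts)
  rate <- ifelse(transcripts$transcript_id %in% truth_bound,
                 config$peak_rate_bound, config$peak_rate_unbound)
  n_peaks <- stats::rpois(n, rate)
  tot <- sum(n_peaks)
  if (tot == 0) return(GenomicRanges::GRanges())
  idx <- rep(seq_len(n), n_peaks)
  width <- sample(30:80, tot, replace = TRUE)
  span_s <- transcripts$span_start[idx]
  span_e <- transcripts$span_end[idx]
  span_w <- span_e - span_s
  in_utr <- stats::runif(tot) < 0.8
  # 3'-terminal 30% of the span: right end on '+', left end on '-'
  plus <- transcripts$strand[idx] == "+"
  lo <- ifelse(in_utr & plus, span_s + floor(0.7 * span_w), span_s)
  hi <- ifelse(in_utr & !plus, span_s + ceiling(0.3 * span_w), span_e)
  lo <- pmin(lo, hi - width)          # keep the peak inside [lo, hi)
  lo <- pmax(lo, span_s)
  start0 <- lo + floor(stats::runif(tot) * pmax(1, hi - width - lo))
  end0 <- pmin(start0 + width, span_e)
  gr <- GenomicRanges::GRanges(
    seqnames = transcripts$chrom[idx],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = transcripts$strand[idx],
    name = sprintf("peak_%05d", seq_len(tot)),
    score = sample(100:1000, tot, replace = TRUE))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
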