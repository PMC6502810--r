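scheme4 <- fraction_scheme(c("free", "mono", "poly1", "poly2"),
                           c("free", "mono", "poly", "poly"))

make_profiles <- function(abund, scheme, genotype = "WT") {
  # abund: named numeric vector over scheme labels, single transcript
  df <- data.frame(transcript_id = "t1", genotype = genotype,
                   fraction = factor(scheme$labels, levels = scheme$labels),
                   abundance = unname(abund[scheme$labels]),
                   pct = 100 * unname(abund[scheme$labels]) / sum(abund),
                   stringsAsFactors = FALSE)
  attr(df, "scheme") <- scheme
  class(df) <- c("fraction_profiles", "data.frame")
  df
}

fraction_cm <- function(counts, labels, genotype = "WT", reps = 1) {
  grid <- expand.grid(rep = seq_len(reps), fraction = labels,
                      stringsAsFactors = FALSE)
  ids <- sprintf("%s_%s_%d", genotype, grid$fraction, grid$rep)
  colnames(counts) <- ids
  count_matrix(counts, data.frame(sample_id = ids,
                                  role = paste0("fraction:", grid$fraction),
                                  genotype = genotype))
}

test_that("fraction schemes are validated", {
  expect_error(fraction_scheme(c("a", "a"), c("free", "mono")), "unique")
  expect_error(fraction_scheme(c("a", "b"), c("free", "light")), "one of")
  expect_error(fraction_scheme(c("a", "b"), c("free", "mono")), "at least one")
})

test_that("uniform abundance yields equal fraction percentages", {
  m <- matrix(100L, nrow = 1, ncol = 4, dimnames = list("t1", NULL))
  cm <- fraction_cm(m, scheme4$labels)
  prof <- normalize_fractions(cm, scheme4, method = "median_of_ratios")
  expect_equal(prof$pct, rep(25, 4))
})

test_that("signal confined to the free fraction yields a 100/0/0 profile", {
  # t1 carries all its signal in the free fraction; t2 anchors normalization
  m <- matrix(c(120L, 0L, 0L, 0L,
                50L, 50L, 50L, 50L), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), NULL))
  cm <- fraction_cm(m, scheme4$labels)
  prof <- normalize_fractions(cm, scheme4, method = "median_of_ratios")
  t1 <- prof[prof$transcript_id == "t1", ]
  expect_equal(t1$pct[t1$fraction == "free"], 100)
  expect_equal(sum(t1$pct), 100)
})

test_that("fraction percentages match an independent per-row recomputation", {
  sim <- sim_config(seed = 701, n_transcripts = 100, n_bound = 10)
  ps <- simulate_polysome(sim)
  prof <- normalize_fractions(ps$counts, sim$scheme, method = "median_of_ratios")
  # manual route: size factors, sweep, replicate means, row percentages
  cm <- ps$counts
  sf <- size_factors(cm, "median_of_ratios")
  norm <- sweep(cm$counts, 2, sf, "/")
  for (tx in sample(rownames(cm$counts), 5)) {
    for (g in c("WT", "KO")) {
      ab <- vapply(sim$scheme$labels, function(lab) {
        cols <- cm$samples$sample_id[cm$samples$genotype == g &
                                       cm$samples$role == paste0("fraction:", lab)]
        mean(norm[tx, cols])
      }, numeric(1))
      want <- 100 * ab / sum(ab)
      got <- prof[prof$transcript_id == tx & prof$genotype == g, ]
      expect_equal(got$pct[match(sim$scheme$labels, as.character(got$fraction))],
                   unname(want))
    }
  }
})

test_that("fraction percentages always sum to 100 for expressed transcripts", {
  sim <- sim_config(seed = 702, n_transcripts = 300, n_bound = 30)
  ps <- simulate_polysome(sim)
  prof <- normalize_fractions(ps$counts, sim$scheme)
  sums <- tapply(prof$pct, interaction(prof$transcript_id, prof$genotype), sum)
  sums <- sums[!is.na(sums)]
  expect_true(all(abs(sums - 100) < 1e-6))
})

test_that("pooled ratios compute poly/free and poly/mono with safe denominators", {
  sc <- fraction_scheme(c("free", "mono", "poly1"), c("free", "mono", "poly"))
  pr <- pooled_ratios(make_profiles(c(free = 20, mono = 20, poly1 = 60), sc))
  expect_equal(pr$te, 3, tolerance = 1e-4)
  expect_equal(pr$poly_mono, 3, tolerance = 1e-4)
  expect_true(pr$defined)

  all_free <- pooled_ratios(make_profiles(c(free = 100, mono = 0, poly1 = 0), sc))
  expect_lt(all_free$te, 1e-3)

  silent <- pooled_ratios(make_profiles(c(free = 0, mono = 0, poly1 = 0), sc))
  expect_false(silent$defined)
  expect_true(is.na(silent$te))
})

test_that("shift classification uses a strict halving threshold", {
  sc <- fraction_scheme(c("free", "mono", "poly1"), c("free", "mono", "poly"))
  mk_ratios <- function(te_wt, te_ko) {
    wt <- make_profiles(c(free = 30, mono = 10, poly1 = 30 * te_wt), sc, "WT")
    ko <- make_profiles(c(free = 30, mono = 10, poly1 = 30 * te_ko), sc, "KO")
    both <- rbind(wt, ko)
    attr(both, "scheme") <- sc
    class(both) <- c("fraction_profiles", "data.frame")
    pooled_ratios(both)
  }
  exactly_half <- classify_shift(mk_ratios(2.0, 1.0))
  expect_equal(exactly_half$group, 2L)  # not strictly below half
  below_half <- classify_shift(mk_ratios(2.0, 0.9))
  expect_equal(below_half$group, 1L)
})

test_that("shift calls are invariant under rescaling a genotype's profile", {
  sim <- sim_config(seed = 703, n_transcripts = 150, n_bound = 15)
  ps <- simulate_polysome(sim)
  prof <- normalize_fractions(ps$counts, sim$scheme)
  base <- classify_shift(pooled_ratios(prof))
  scaled <- prof
  scaled$abundance[scaled$genotype == "KO"] <-
    scaled$abundance[scaled$genotype == "KO"] * 7.3
  attr(scaled, "scheme") <- sim$scheme
  class(scaled) <- c("fraction_profiles", "data.frame")
  rescored <- classify_shift(pooled_ratios(scaled))
  expect_equal(rescored$group, base$group)
})

test_that("raising the shift threshold never shrinks group 1", {
  sim <- sim_config(seed = 704, n_transcripts = 400, n_bound = 40)
  ps <- simulate_polysome(sim)
  ratios <- pooled_ratios(normalize_fractions(ps$counts, sim$scheme))
  g1 <- function(th) {
    calls <- classify_shift(ratios, threshold = th)
    calls$transcript_id[!is.na(calls$group) & calls$group == 1L]
  }
  expect_true(all(g1(0.5) %in% g1(0.7)))
  expect_true(all(g1(0.7) %in% g1(0.9)))
})

test_that("planted initiation blocks are recovered in ratio and rate", {
  sim <- sim_config(seed = 11)
  ps <- simulate_polysome(sim)
  calls <- classify_shift(pooled_ratios(normalize_fractions(ps$counts, sim$scheme)))
  shifted <- calls$transcript_id %in% ps$truth_shifted
  # planted te_ko/te_wt from the class means: 0.25 * f / (f + 0.75 * e)
  planted <- 0.25 * 0.2 / (0.2 + 0.75 * 0.8)
  med <- median(calls$te_ko[shifted] / calls$te_wt[shifted])
  expect_lt(abs(med / planted - 1), 0.10)
  # poly:mono ratio is preserved for shifted transcripts (initiation, not elongation)
  pm <- median(calls$poly_mono_ko[shifted] / calls$poly_mono_wt[shifted],
               na.rm = TRUE)
  expect_lt(abs(pm - 1), 0.05)
  # group-1 rate within 3 points of the planted 30%
  expect_lt(abs(100 * mean(calls$group == 1L, na.rm = TRUE) - 30), 3)
})

test_that("shift enrichment reduces to the chi-square oracle on its counts", {
  sim <- sim_config(seed = 705, n_transcripts = 600, n_bound = 60)
  rip <- simulate_ripseq(sim)
  ps <- simulate_polysome(sim, rip$truth_bound)
  calls <- classify_shift(pooled_ratios(normalize_fractions(ps$counts, sim$scheme)))
  se <- shift_enrichment(calls, rip$truth_bound)
  ok <- calls[!is.na(calls$group), ]
  ref <- goodness_of_fit_chisq(se$k_bound_group1, se$n_bound,
                               mean(ok$group == 1L))
  expect_equal(se$test$statistic, ref$statistic)
  expect_equal(se$test$p_value, ref$p_value)
})

test_that("a bound set with the global group-1 share gives p = 1", {
  ratios <- structure(data.frame(
    transcript_id = rep(sprintf("t%03d", 1:100), 2),
    genotype = rep(c("WT", "KO"), each = 100),
    free = 10, mono = 10,
    poly = c(rep(30, 100), rep(c(3, 30), times = c(20, 80))),
    te = c(rep(3, 100), rep(c(0.3, 3), times = c(20, 80))),
    poly_mono = 3, defined = TRUE, stringsAsFactors = FALSE),
    class = c("pooled_ratios", "data.frame"))
  calls <- classify_shift(ratios)
  # global group-1 share is 20%; pick 10 bound with exactly 2 in group 1
  bound <- c(sprintf("t%03d", 1:2), sprintf("t%03d", 30:37))
  se <- shift_enrichment(calls, bound)
  expect_equal(se$test$statistic, 0)
  expect_equal(se$test$p_value, 1)
})
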