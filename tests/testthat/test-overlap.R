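test_that("binder-set intersection reports published-style percentages", {
  u <- sprintf("t%05d", 1:12388)
  a <- binder_set(u[1:837], 12388)
  b <- binder_set(u[c(1:755, 2000:2996)], 12388)  # 1752 members, 755 shared
  ov <- intersect_binders(a, b)
  expect_equal(ov$size_intersection, 755L)
  expect_equal(ov$pct_of_a, 90)
  expect_equal(ov$size_b, 1752L)

  disjoint <- intersect_binders(binder_set(u[1:10], 100),
                                binder_set(u[11:20], 100))
  expect_equal(disjoint$size_intersection, 0L)
  expect_equal(disjoint$pct_of_a, 0)

  expect_error(intersect_binders(binder_set(character(0), 10),
                                 binder_set(u[1:5], 10)), "empty")
})

test_that("intersection equals a brute-force membership loop and is symmetric", {
  set.seed(601)
  u <- sprintf("t%03d", 1:200)
  for (i in 1:10) {
    a <- binder_set(sample(u, 50), 200)
    b <- binder_set(sample(u, 80), 200)
    ov <- intersect_binders(a, b)
    brute <- sum(vapply(a$members, function(x) x %in% b$members, logical(1)))
    expect_equal(ov$size_intersection, brute)
    ba <- intersect_binders(b, a)
    expect_equal(ba$size_intersection, ov$size_intersection)
    expect_equal(ba$pct_of_a, ov$pct_of_b)
  }
})

test_that("transcriptome fraction rounds half away from zero", {
  expect_equal(transcriptome_fraction(binder_set(sprintf("t%d", 1:837), 12388)), 7)
  expect_equal(transcriptome_fraction(binder_set(sprintf("t%d", 1:50), 50)), 100)
  expect_equal(transcriptome_fraction(binder_set("t1", 3)), 33)
  expect_equal(transcriptome_fraction(binder_set("t1", 2)), 50)
})

test_that("coverage respects half-open boundaries and span/exonic modes", {
  tt <- toy_transcripts()
  # tA span is [100, 200); a peak starting at 200 abuts but does not overlap
  abutting <- peaks_granges(data.frame(chrom = "chr1", start = 200, end = 210,
                                       strand = "+"))
  cov <- clip_coverage("tA", abutting, tt)
  expect_equal(cov$n_covered, 0L)

  touching <- peaks_granges(data.frame(chrom = "chr1", start = 199, end = 210,
                                       strand = "+"))
  expect_equal(clip_coverage("tA", touching, tt)$n_covered, 1L)

  # tB has an intron at [1100, 1300)
  intronic <- peaks_granges(data.frame(chrom = "chr1", start = 1150, end = 1200,
                                       strand = "-"))
  expect_equal(clip_coverage("tB", intronic, tt, mode = "span")$n_covered, 1L)
  expect_equal(clip_coverage("tB", intronic, tt, mode = "exonic")$n_covered, 0L)
})

test_that("strand matching honors strand-agnostic peaks", {
  tt <- toy_transcripts()
  minus_peak <- peaks_granges(data.frame(chrom = "chr1", start = 150, end = 160,
                                         strand = "-"))
  star_peak <- peaks_granges(data.frame(chrom = "chr1", start = 150, end = 160,
                                        strand = "*"))
  expect_equal(clip_coverage("tA", minus_peak, tt, strand_mode = "matched")$n_covered, 0L)
  expect_equal(clip_coverage("tA", minus_peak, tt, strand_mode = "ignore")$n_covered, 1L)
  expect_equal(clip_coverage("tA", star_peak, tt, strand_mode = "matched")$n_covered, 1L)
})

test_that("coverage equals the exhaustive overlap loop on random instances", {
  sim <- sim_config(seed = 602, n_transcripts = 100, n_bound = 20)
  tt <- simulate_ripseq(sim)$transcripts
  set.seed(603)
  n_peaks <- 500
  idx <- sample(nrow(tt), n_peaks, replace = TRUE)
  offs <- floor(runif(n_peaks, -200, (tt$span_end - tt$span_start)[idx] + 200))
  start <- tt$span_start[idx] + offs
  peaks_df <- data.frame(chrom = tt$chrom[idx],
                         start = start,
                         end = start + sample(20:120, n_peaks, replace = TRUE),
                         strand = sample(c("+", "-", "*"), n_peaks, replace = TRUE))
  gr <- peaks_granges(peaks_df)
  ids <- tt$transcript_id
  for (mode in c("span", "exonic")) {
    for (sm in c("matched", "ignore")) {
      got <- clip_coverage(ids, gr, tt, mode = mode, strand_mode = sm)
      want <- brute_force_coverage(ids, tt, peaks_df, mode, sm)
      expect_setequal(got$covered_ids, want)
      expect_equal(got$n_covered, length(want))
    }
  }
})

test_that("exonic coverage is a subset of span coverage", {
  sim <- sim_config(seed = 604, n_transcripts = 60, n_bound = 30)
  rip <- simulate_ripseq(sim)
  peaks <- simulate_eclip(sim, rip$transcripts, rip$truth_bound)
  ids <- rip$transcripts$transcript_id
  ex <- clip_coverage(ids, peaks, rip$transcripts, mode = "exonic")
  sp <- clip_coverage(ids, peaks, rip$transcripts, mode = "span")
  expect_true(all(ex$covered_ids %in% sp$covered_ids))
})

test_that("goodness-of-fit chi-square matches hand values and symmetry", {
  fit <- goodness_of_fit_chisq(50, 100, 0.5)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p_value, 1)

  hand <- goodness_of_fit_chisq(70, 100, 0.5)
  expect_equal(hand$statistic, 16)  # 20^2/50 + 20^2/50
  expect_equal(hand$df, 1L)

  a <- goodness_of_fit_chisq(37, 120, 0.22)
  b <- goodness_of_fit_chisq(120 - 37, 120, 1 - 0.22)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)

  expect_error(goodness_of_fit_chisq(5, 10, 0), "strictly")
  expect_error(goodness_of_fit_chisq(11, 10, 0.5), "k must be")
})

test_that("chi-square statistic and p-value agree with stats::chisq.test", {
  set.seed(605)
  for (i in 1:25) {
    n <- sample(10:5000, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    got <- goodness_of_fit_chisq(k, n, p)
    ref <- suppressWarnings(stats::chisq.test(c(k, n - k), p = c(p, 1 - p),
                                              correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    if (ref$p.value > 1e-280) {
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})
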