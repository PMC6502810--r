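# ribostate

Quantitative analysis linking what an RNA-binding protein binds to how it
regulates translation initiation — and whether the same factor's
transcriptional arm shows up as concordant differential expression.

## Who this is for

Groups doing RIP-seq plus polysome profiling on a wild-type/knockout pair
of cell lines, who need to (i) call the protein's transcript targets from
IP-vs-control count tables, (ii) quantify how knockout redistributes each
mRNA across free/monosome/polysome fractions, (iii) test whether bound
transcripts are over-represented among translationally impaired ones, and
(iv) intersect two knockout DE contrasts direction-aware. All stages
consume plain count tables (TSV), annotations (GTF), peak intervals (BED)
and DE result tables; no read-level processing is involved.

## The statistics at the core

* **Binder calling.** Adjusted FPKM
  `(c_ij / s_j) * 1e9 / (L_i * N)` with DESeq-style size factors `s_j` and
  a common effective library size `N` (geometric mean of corrected library
  sums); fold enrichment `(mean_IP + 1) / (mean_ctrl + 1)` over replicate
  means; binders are detected transcripts strictly above the cutoff
  (default > 4-fold).
* **Translation shift.** Per-fraction normalization (with an iterated
  stable-reference refinement of median-of-ratios that stays calibrated
  when a large minority of transcripts shifts), per-transcript fraction
  percentages, pooled ratios `te = poly/free` and `poly/mono`; group 1 =
  `te_KO < 0.5 * te_WT` (strict).
* **Enrichment.** One-sample Pearson goodness-of-fit chi-square (df = 1,
  no continuity correction) of the group-1 count among bound transcripts
  against the global group-1 proportion.
* **Concordance.** Inclusive filters `padj <= 0.05`, `|log2fc| >= 1`
  applied to both contrasts; intersection restricted to matching sign,
  split into jointly up / jointly down.
* **Synthetic truth.** Negative-binomial generators plant each effect
  (bound subset, initiation block preserving poly:mono, concordant DE
  subset, 3'-biased CLIP peaks) for parameter-recovery testing.

Details and rationale: `vignettes/ribostate-methods.Rmd`.

## Worked example

Set arithmetic on published-scale binder counts:

```r
library(ribostate)
u <- sprintf("t%05d", 1:12388)
cbfb   <- binder_set(u[1:837], universe_size = 12388)
hnrnpk <- binder_set(u[c(1:755, 3000:3996)], universe_size = 12388)
intersect_binders(cbfb, hnrnpk)
#> overlap: |A|=837, |B|=1752, |A&B|=755 (90% of A, 43% of B)
transcriptome_fraction(cbfb)
#> [1] 7
```

The full synthetic demo — simulate, call binders, overlay CLIP peaks,
classify translation shifts, test enrichment, intersect DE tables:

```r
report <- run_pipeline(run_config(seed = 1))
print(report)
#> == synthetic pipeline report (seed 1 ) ==
#> RIP-seq: 97 binders (fold > 4) of 2000 detected (5% of transcriptome); sensitivity 0.970, observed FDR 0.000
#> CLIP: 85 / 97 binders covered by >= 1 peak (88%), 548 peaks
#> Polysome: group 1 = 32% globally (n=2000), 74% among binders (n=97); X2 = 78.98, p = 6.28e-19
#> Concordant DE: 212 genes (138 up, 74 down) from 658 / 393 filtered
```

Reading the report: 97 of the 100 planted bound transcripts are recovered
at the 4-fold cutoff with no false calls; the planted 30% initiation-block
rate is estimated at 32% transcriptome-wide, rising to 74% among binders
(the planted 3x association), with the chi-square rejecting independence
at p ~ 6e-19; the planted concordant DE subset (138 up + 74 down) is
recovered exactly.

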