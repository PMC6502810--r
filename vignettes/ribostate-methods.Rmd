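---
title: "From RNA binding to translation initiation: the ribostate methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RNA binding to translation initiation: the ribostate methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostate)
```

## The scientific problem

An RNA-binding regulator of translation initiation leaves three measurable
footprints. First, its transcript targets are enriched in an RNA
immunoprecipitation (RIP-seq) library relative to a control
immunoprecipitation. Second, when the regulator is knocked out, target
mRNAs fall off polysomes: in sucrose-gradient polysome profiling their mass
redistributes from the polysome fractions to the free-mRNP fraction, while
the ratio of polysome to monosome signal among the mRNA still engaged with
ribosomes stays put — the signature of an initiation block rather than an
elongation defect. Third, if the regulator also acts in the nucleus, two
knockout contrasts (the regulator and its transcriptional partner) share a
direction-concordant set of differentially expressed genes.

`ribostate` implements this three-legged analysis as composable stages —
binder calling, fraction-profile analysis with shift classification and a
chi-square enrichment of shifts among binders, CLIP-peak coverage, and
concordant DE intersection — together with generators that plant each
effect in synthetic data so every stage can be validated by parameter
recovery.

## Binder calling from RIP-seq counts

Counts are normalized in two steps. Per-sample size factors come from the
DESeq median-of-ratios estimator (or simple counts-per-million). Adjusted
FPKM is then

$$\mathrm{FPKM}_{ij} = \frac{c_{ij}/s_j}{L_i \cdot N} \times 10^9,$$

where $c_{ij}$ is the raw count, $s_j$ the sample's size factor, $L_i$ the
transcript length (summed exon length when exon structure is available),
and $N$ a single *effective library size* shared by all samples: the
geometric mean over samples of $\sum_i c_{ij}/s_j$. Using one common $N$
rather than each sample's own raw library sum matters: an IP library whose
bound targets are strongly enriched has an inflated total, and dividing by
it would deflate every IP value and drag fold enrichments toward 1 (with a
planted 8-fold effect and ~5% bound transcripts the compression is ~35%).
The shared-$N$ convention is the same robust choice DESeq2 makes in its
`fpkm()`.

Per-transcript enrichment is the pseudocounted ratio of role means,
$(\bar{x}_\mathrm{IP} + 1)/(\bar{x}_\mathrm{ctrl} + 1)$, with means taken
on the FPKM scale across replicates. A transcript is *detected* when
either role mean reaches the detection floor (default adjusted FPKM of 1);
the floor exists because ratios between two near-zero numbers are noise.
Binders are detected transcripts with enrichment strictly greater than the
cutoff (default 4, "more than 4-fold"); the strict inequality also
guarantees the monotonicity used downstream (the set at cutoff 2 always
contains the set at cutoff 4).

Both the pseudocount and the floor are configurable through
`norm_config()`; percentages reported by the set operations are rounded
half away from zero, as printed percentages conventionally are, while full
precision is kept internally.

## Fraction profiles and the translation-efficiency shift

A `fraction_scheme()` orders the gradient fractions and assigns each to a
class: `free` (mRNPs not engaged by ribosomes), `mono` (the 80S monosome)
or `poly` (everything heavier, pooled by summation). The default scheme
has one free, one mono and three poly fractions; sub-80S (40S/60S)
fractions, if present in a dataset, should be mapped to `free`, since they
carry no elongating ribosome.

Each fraction sample is its own library, so normalization across fraction
samples is the step that decides whether genotype comparisons are
meaningful. Plain median-of-ratios has a known failure mode here: when a
sizeable minority of transcripts (tens of percent) coherently loses
engaged mass in one genotype, the median in the affected libraries no
longer sits on unchanged transcripts — it lands on a contaminated flank of
the ratio distribution and the estimated factors compress every
between-genotype ratio. The default `"stable_reference"` method therefore
iterates: compute factors, form each transcript's between-genotype
poly/free ratio, find the mode of the log-ratio distribution (the
translationally stable majority), restrict the median-of-ratios reference
to transcripts within 2-fold of that mode, and repeat (convergence is
typically reached on the second pass). This is the same idea as DESeq2's
`controlGenes`, with the control set identified automatically. With a
single genotype, or fewer than 20 transcripts, the method falls back to
plain median-of-ratios; both plain methods remain selectable.

From normalized profiles the package reports, per transcript and genotype,
the percentage of the transcript's own total in each fraction (summing to
100 whenever the total is positive), and two pooled ratios: the
translation-efficiency proxy $\mathrm{te} = \mathrm{poly}/\mathrm{free}$
and the elongation proxy $\mathrm{poly}/\mathrm{mono}$. Denominators carry
a pseudo-term of $10^{-6}$ of the transcript's total, so a transcript
absent from the denominator class yields a large-but-finite ratio, while a
transcript with zero total in a genotype is flagged undefined, excluded
from classification and counted in the call table rather than silently
dropped.

A transcript is *group 1* (initiation-impaired) when
$\mathrm{te}_{KO} < \theta\,\mathrm{te}_{WT}$ strictly, with $\theta = 0.5$
("decreased by more than half"); equality at the boundary is group 2.
Whether bound transcripts are over-represented in group 1 is tested with a
one-sample Pearson goodness-of-fit chi-square (1 df, no continuity
correction, upper-tail p): the global group-1 proportion over all
classified transcripts is the expected proportion for the bound subset.
This matches a design where the bound set is compared against a
transcriptome-wide expectation; a 2x2 contingency test between bound and
unbound would be the alternative had the universe been partitioned, but
the one-sample form is what a stated "expected percentage based on global
mRNAs" describes.

## Concordant differential expression

DE tables (gene, log2 fold change of knockout vs wild type, adjusted p)
are consumed, not fitted — the package does not reimplement DESeq. The
filters are inclusive, `padj <= fdr` and `|log2fc| >= log2(fold)` (defaults
0.05 and 2): with thresholds quoted as "at FDR = 0.05", inclusion is the
reading that keeps a gene sitting exactly on the threshold. The concordant
set is the intersection of the two filtered sets restricted to equal sign,
split into jointly-up and jointly-down; by construction
`n_up + n_down = n_concordant` and the operation is symmetric in its
inputs. Note the sign convention: a gene *induced* by the regulator is
*down* in the knockout contrast.

## CLIP-peak coverage

Peak intervals (BED) are held as `GRanges` and intersected with transcript
spans (default) or exon structures; a transcript is covered by at least
one peak overlapping it by at least 1 bp — no minimum-fraction rule,
because the claim being operationalized is "has at least one site". The
default matches strand, treating strandless BED records as compatible with
either strand; both the mode and the strand handling are arguments, since
published descriptions of such intersections rarely pin them down. The
package keeps 0-based half-open coordinates at its own interfaces
(transcript records, poly-C tract positions, BED/GTF files) and converts
at the `GRanges` boundary, so the half-open boundary semantics are
preserved: a peak that starts exactly at a span's end does not overlap it.

The poly-C tract scanner (`find_polyc_tracts()`) reports maximal runs of C
of a minimum length, case-insensitively, with U treated as T and N never
matching — the substrate definition for poly-C-binding proteins such as
hnRNPK.

## The synthetic-data generators

The generators exist to make every stage testable with known ground
truth. They emulate, with standard distributional choices, exactly the
effect structure the stages assume:

* **RIP-seq** (`simulate_ripseq`): lognormal baseline means
  (meanlog $= \log 200$, sdlog 1 — a realistic bulk RNA-seq abundance
  spread), negative-binomial counts at dispersion 0.1, per-sample depth
  factors lognormal (sdlog 0.2), 3 replicates per role; 100 of 2000
  transcripts have IP means multiplied by the planted fold (default 8).
* **Polysome profiling** (`simulate_polysome`): each transcript's
  fraction proportions are a Dirichlet draw around class means (free 20%,
  mono 20%, poly 60%), concentration 150 — tight enough to mimic the
  reproducibility of fractionation replicates. In the knockout, a planted
  30% of transcripts moves 75% of its *engaged* (mono + poly) mass to the
  free fraction, leaving within-engaged proportions untouched, so
  poly:mono is preserved by construction; bound transcripts are 3x as
  likely to be shifted. Counts are negative binomial on top.
* **DE tables** (`simulate_de`): a planted concordant subset (default
  138 up + 74 down) passes both filters with matching signs; decoys fail
  the FDR filter, the fold filter, agree in significance but not in
  direction, or are significant in one contrast only — so truth recovery
  is exact, not approximate.
* **CLIP peaks** (`simulate_eclip`): Poisson peak counts per transcript
  (means 2 bound / 0.2 unbound), peaks of 30-80 bp placed inside the
  span with an 80% bias to the strand-aware 3'-terminal 30%, mirroring
  3'-UTR binding.

All generators are pure functions of their `sim_config()` (the seed is
part of the config), which is what makes the recovery tests and the demo
pipeline exactly reproducible. What the generators deliberately do *not*
model: correlated dispersion-mean trends, GC or length biases, multimapping
ambiguity, isoform-level signal redistribution, or partial-digestion
artifacts of fractionation. Passing recovery tests therefore demonstrate
that the estimators are correct and well-calibrated under the stated
statistical structure, not that real libraries meet that structure.

## Problem sizes and numerical choices

The test suite and the demo pipeline run at 2000 transcripts, 3 replicates
per role and 5 fractions x 2 genotypes — sizes at which every recovery
margin (binder sensitivity, group-1 calibration, enrichment p-values) is
stable across seeds while the whole suite completes in well under a
minute of compute. Oracle-equivalence tests run interval overlap against
an exhaustive double loop (500 peaks x 100 transcripts), the chi-square
against `stats::chisq.test`, and FPKM against literal per-cell
recomputation.

Remaining numerical conventions, collected: percentages round half away
from zero; binder and shift thresholds are strict inequalities; detection
and classification never clamp — malformed coordinates, negative or
non-integer counts, missing lengths and undefined ratios are errors or
flagged exclusions, not silent fixes.

## Interface

The package is used from R: readers (`read_counts`, `read_gtf`,
`read_bed`, `read_de_table`), per-stage functions, and
`run_pipeline(run_config(seed = ...))`, which chains
simulate → binder calling → coverage → shift classification → enrichment →
concordance and returns (optionally writes as JSON) a report with every
stage's counts, percentages and statistics.

```{r demo, eval = FALSE}
report <- run_pipeline(run_config(seed = 1))
print(report)
```

## Known limitations

Fraction-level normalization assumes a translationally stable majority of
transcripts; if more than half the transcriptome shifted, the stable
reference would be unidentifiable without spike-ins (which are out of
scope). The chi-square enrichment treats transcripts as independent
draws, as the one-sample design implies. Binder calling uses a fold
cutoff, not a per-transcript test, so no binder-level error control is
attached beyond what the recovery simulations measure. Gene- vs
transcript-level identifier mixing is the caller's responsibility: the
concordance stage assumes comparable identifiers across the two tables.
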