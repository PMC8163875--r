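---
title: "Quantifying intron retention from junction read classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention from junction read classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceretain)
```

## The problem

When a spliceosomal component is perturbed — for instance when the single
m^6^A modification of U6 snRNA is lost in a fission-yeast methyltransferase
knockout — a subset of introns is retained in mature poly(A)^+^ transcripts.
`spliceretain` quantifies this from spliced RNA-seq alignments, identifies
which introns are sensitive, and characterizes the splice-site sequence
features (the fourth intron nucleotide facing the U6 m^6^A, and the 5′-exon
terminal triplet read by U5 snRNA loop I) that predict sensitivity.

## Read classification

For each *segment* — an annotated intron with its two flanking exons — every
primary alignment is assigned to exactly one of five classes:

* **EIJR** — contiguous alignment across the transcriptional 5′ splice site
  (pre-mRNA evidence at the donor);
* **IEJR** — contiguous alignment across the 3′ splice site;
* **CSR** — alignment whose N-gap coincides exactly with the annotated
  intron (spliced mRNA evidence);
* **A5R / A3R** — gapped alignments using the annotated acceptor (donor)
  together with an alternative donor (acceptor) inside the segment;
* **NONE** — anything else, including purely exonic or purely intronic
  alignments.

Every junction must be flanked by at least `min_overhang` aligned
nucleotides on both sides (default 8 nt, matching common aligner splice
junction overhang settings; we apply the same rule to all five classes).
Coordinates are 0-based half-open internally, converting GFF3/GTF input on
read, so junction arithmetic is exact. Classification is strand-aware: the
5′ splice site is `intron_start` on the plus strand and `intron_end` on the
minus strand, which makes all class counts invariant under
reverse-complementing a locus. Where a read satisfies several rules (a long
contiguous read over a very short intron can span both boundaries) the
precedence CSR > A5R > A3R > EIJR > IEJR makes the label unique and
deterministic. Each mate of a pair is counted independently; secondary and
supplementary alignments are skipped.

## Metrics

With `cov(x)` the read count of class `x` in one sample:

* `cov(Total) = (cov(EIJR) + cov(IEJR))/2 + cov(A5R) + cov(A3R) + cov(CSR)`.
  The two boundary classes each observe only one of the intron's two
  junctions, so their mean estimates retained-isoform coverage.
* **IRS** (intron retention score)
  `= log2((cov(EIJR) + cov(IEJR) + 0.1) / (2 cov(CSR) + 0.1))`. The 0.1
  pseudocount keeps the score finite at zero counts; it is deliberately not
  configurable so scores remain comparable across analyses. IRS is exactly 0
  at the balance point `eijr + iejr = 2 csr`.
* **PCS** (proportion of canonical splicing) `= cov(CSR)/cov(Total)`,
  undefined (`NA`, never imputed) at zero total coverage.

Replicate IRS values are compared between conditions by a two-sample
Z-score, `(mu_KO - mu_WT) / sqrt(sigma_KO^2/n + sigma_WT^2/n)`. We use
sample (n−1) variances — the printed quadruplicate form divides both
variances by 4 and does not pin down the estimator; sample variance is the
standard two-sample convention — and generalize to arbitrary replicate
numbers. When both variances vanish, the score is 0 for equal means and a
signed infinity sentinel otherwise, so such introns sort to the extremes
rather than being dropped.

Introns enter the comparison when they are GY-AG (donor G followed by a
pyrimidine; acceptor AG), have `cov(Total) > 10` in **every** replicate of
both conditions, and mean CSR `> 10` in at least one condition. Both
thresholds are strict inequalities. Eligible introns are then ranked by Z
and partitioned at the quartiles: `high` is strictly above the 75th
percentile of Z, `low` strictly below the 25th (type-7 quantiles). Strict
comparison makes the partition deterministic under ties — boundary-tied
values fall into `mid`, and a fully tied input yields empty extreme sets —
and with distinct values selects exactly `floor(n/4)` introns on each side.

Per-intron IRS can be reported two ways: the replicate mean (used for the
Z-score and for ΔIRS) and the IRS of pooled counts. We compute metrics per
sample and aggregate, so both are available; all group comparisons in this
package use replicate means.

## Sequence characterization

Splice-site windows default to exon −3..−1 plus intron +1..+6 at the 5′SS
and intron −6..−1 plus exon +1..+3 at the 3′SS — wide enough to cover the
donor consensus (GTAAGT), the fourth nucleotide, and the 5′-exon triplet —
and are configurable. Sequence logos use the classic information content
`2 − H` bits per column with no small-sample correction; difference logos
use the per-column Jensen–Shannon divergence (base 2) with per-nucleotide
contributions proportional to `p_high − p_low`, rescaled so absolute
contributions sum to the divergence. Positional enrichment of a focal
nucleotide between the high-Z and low-Z sets is tested by a two-sided
Fisher exact test, computed by direct hypergeometric summation (all tables
no more probable than the observed one, with the conventional 1e-7 relative
tolerance for numerical ties); the focal nucleotide is a parameter because
either a single base or a pooled complement can meaningfully be tested at
exonic positions.

Introns are grouped by the fourth intron nucleotide (A4/T4/C4/G4) and by
the 5′-exon terminal triplet encoded against the AAG consensus (positions
−3/−2 as A or B = non-A; position −1 as G or H = non-G), giving AAG plus
the seven non-consensus patterns. Group ΔIRS distributions are compared by
two-sided Wilcoxon rank-sum tests — exact when both groups have at most 50
tie-free observations, normal approximation with continuity and tie
correction otherwise — alongside empirical CDFs and quartile/1.5×IQR box
summaries.

## Splicing-adjusted expression

For differential expression downstream, raw gene counts are multiplied by
the product of PCS values of the gene's CDS introns in the same sample
(UTR introns are excluded; CDS membership is taken from annotation CDS
features as the span from the gene's first to last CDS base). A missing PCS
(an intron with no informative coverage in that sample) contributes a
factor of 1 and is counted in a warning rather than being imputed — an
intron we cannot measure should not move the expression estimate. Adjusted
counts are left as reals; rounding is the concern of the downstream tool.

## The synthetic-data generator

The generator emulates the study design so the whole pipeline can be
exercised and validated without any download: quadruplicate samples in two
conditions, one GY-AG intron per gene, a fourth-nucleotide composition of
A/T/C/G = 0.50/0.36/0.10/0.04 (matching the relative sizes of the observed
A4/T4/C4/G4 groups), an AAG-triplet fraction of 0.11 (the observed AAG-A4
share among A4 introns), and genes placed on both strands. Baseline
retention odds are lognormal with median 0.05 — a well-spliced baseline IRS
around −4.3 — with spread 0.5 on the log scale; informative depth is
lognormal with mean 500 fragments per intron and negative-binomial
replicate noise with dispersion 0.1, a typical bulk RNA-seq overdispersion.
The knockout multiplies retention odds by class: ×6 for A4, ×3 for C4,
×1.2 for G4, ×1 for T4, applied only to non-AAG introns (AAG introns are
protected). These defaults *are* the study conditions used by the tests and
the acceptance script; they were chosen once and are not tuned.

The count model keeps the metrics analytically transparent: per replicate,
`T` molecules are drawn (negative binomial), a fraction `r = odds/(1+odds)`
is retained, spliced molecules each yield one CSR read, and each retained
pre-mRNA yields one read at each boundary, split binomially between EIJR
and IEJR. Hence `cov(Total) = T` exactly, the boundary-to-spliced ratio
estimates the odds, and IRS concentrates at `log2(odds)`. The read-level
emitter realizes any count table as a valid SAM file whose alignments
classify back to their generating class exactly, placing junction reads
inside their segment so labels are unique.

What the simulator does **not** model: sequencing error, mappability and
multi-mapping, fragment-length effects, positional coverage bias,
annotation errors, and expression change induced by retention itself.
Passing tests therefore demonstrate correctness of the computation and
qualitative recoverability of the retention structure, not performance on
real libraries.

## Calibration note on the null Z-scores

With four replicates per condition the two-sample Z statistic uses
estimated variances and is approximately t-distributed with ~6 degrees of
freedom, whose two-sided 1.96 tail is ≈ 9.8 % rather than the nominal 5 %.
The null-simulation test therefore accepts an exceedance fraction in
(0.02, 0.15), a band containing both the nominal and the small-sample
reference rates; the observed fraction lands near the t-reference, as
expected. Selecting extreme introns by Z *quartiles* rather than by a
p-value threshold — as this pipeline does — is insensitive to this
inflation.

## Problem sizes and numerical choices

Tests and the acceptance script run the generator at its default 2,000
introns with depth 500 and 4+4 replicates, the formula oracles at 1,000
random count vectors, the Fisher enumeration over all 2×2 tables with
margins ≤ 30, and the read-level round trip at 200 segments on both
strands. Degenerate inputs are handled explicitly: empty alignment streams
give all-zero tables; introns shorter than the window are skipped with a
warning; zero-coverage PCS propagates as missing; all-tied Z-scores give
empty extreme quartiles; empty Fisher margins give p = 1.

## Worked example

```{r example, eval = FALSE}
ref <- generate_reference(sim_config(), seed = 1)
counts <- simulate_junction_counts(ref, seed = 2)
samples <- sim_sample_sheet()
segments <- extract_intron_segments(ref$annotation, ref$genome)

metrics <- compute_splicing_metrics(counts)
eligible <- filter_introns(counts, segments, samples)
z <- summarize_zscores(metrics, samples, eligible = eligible)
partition <- quartile_partition(z[, c("segment_id", "z")])

d <- delta_irs(metrics, samples)
groups <- classify_fourth_nucleotide(segments)
comparison <- group_compare(
  d$delta[match(eligible, d$segment_id)],
  groups[match(eligible, segments$segment_id)])
comparison$medians
```

## Limitations

The A5R/A3R bookkeeping restricts alternative sites to within the segment
and does not attempt novel-intron discovery; mate-pair co-counting is not
modeled (each mate counts once, so a pair spanning the same junction
contributes two reads); and multi-mapper weighting is not implemented —
alignments are taken at face value after the secondary/supplementary
filter. The differential-expression test itself and any enrichment analysis
of gene lists are outside the package's scope: `adjust_table` produces the
input matrix a count-based DE tool expects.
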