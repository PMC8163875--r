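# spliceretain

Intron retention quantification and splice-site characterization from
spliced RNA-seq alignments.

When splicing is perturbed — the motivating case is a fission-yeast strain
whose U6 snRNA lacks its single m^6^A modification, the base that pairs
with intron position +4 during catalysis — a subset of introns is retained
in poly(A)^+^ transcripts. `spliceretain` measures this per intron and per
sample, tests which introns respond between two conditions, and relates
sensitivity to splice-site sequence: the fourth intron nucleotide
(A4/T4/C4/G4 groups) and the 5′-exon terminal triplet read by U5 snRNA
loop I (AAG consensus versus the seven non-consensus patterns).

## Method

For each annotated intron with its flanking exons, primary alignments are
classified into five junction classes — exon–intron (EIJR), intron–exon
(IEJR), canonical spliced (CSR), and alternative 5′/3′ splice-site reads
(A5R/A3R) — requiring ≥ 8 aligned nt on both sides of any junction. Per
intron and sample:

    cov(Total) = (cov(EIJR) + cov(IEJR))/2 + cov(A5R) + cov(A3R) + cov(CSR)
    IRS = log2( (cov(EIJR) + cov(IEJR) + 0.1) / (2·cov(CSR) + 0.1) )
    PCS = cov(CSR) / cov(Total)

Replicate IRS values are compared between conditions with a two-sample
Z-score, Z = (μ_KO − μ_WT) / √(σ²_KO/n + σ²_WT/n); eligible GY-AG introns
(cov(Total) > 10 in all replicates, mean CSR > 10 in either condition) are
ranked by Z and split at the quartiles. The extreme quartiles are compared
by information-content logos, Jensen–Shannon difference logos, and
two-sided Fisher exact tests per splice-site position; group ΔIRS
(mean IRS difference, knockout − wild type) is compared by Wilcoxon
rank-sum tests. Gene counts can be corrected for splicing with
adjusted = raw · Π PCS_k over the gene's CDS introns, for downstream
differential-expression tools.

A synthetic-data module generates genomes, annotations, ground-truth
retention parameters, junction counts and spliced SAM reads under the
quadruplicate two-condition design, so the full pipeline runs and is
validated offline.

## Worked example

```r
library(spliceretain)

ref      <- generate_reference(sim_config(), seed = 1)   # 2000 introns
counts   <- simulate_junction_counts(ref, seed = 2)      # 4 WT + 4 KO
samples  <- sim_sample_sheet()
segments <- extract_intron_segments(ref$annotation, ref$genome)

metrics  <- compute_splicing_metrics(counts)
eligible <- filter_introns(counts, segments, samples)
z        <- summarize_zscores(metrics, samples, eligible = eligible)

d      <- delta_irs(metrics, samples)
groups <- classify_fourth_nucleotide(segments)
cmp    <- group_compare(d$delta[match(eligible, d$segment_id)],
                        groups[match(eligible, segments$segment_id)])
round(unlist(cmp$medians), 3)
#>    A4    T4    C4    G4
#> 2.565 0.009 1.553 0.190
head(cmp$pvalues, 2)
#>   group1 group2             p
#> 1     A4     T4 1.366999e-211
#> 2     A4     C4  1.508379e-73
```

The median ΔIRS per group recovers the injected knockout effect structure:
A4 introns retain most strongly, C4 intermediately, and T4/G4 barely move;
the rank-sum p-values quantify the separations. The most responsive introns
(e.g. `z` sorted descending: μ_WT −4.61 → μ_KO −1.95, Z ≈ 63.8) are the
candidates one would validate by intron-specific RT-PCR.

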