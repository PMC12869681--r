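# svcohort

Harmonization, quality control and case-control association analysis of
structural variants (SVs) called per sample from whole-genome sequencing.

Modern sequence-resolved SV callers emit one VCF per genome with explicit
REF/ALT allele sequences and a per-record quality score. Turning thousands of
such call sets into one analysis-ready cohort requires deciding when two
calls describe the same event, how stringent the quality filter should be,
which samples and studies are technically aberrant, and how to test the
resulting sites — common ones individually, rare ones aggregated per gene —
for association with a binary phenotype such as late-onset Alzheimer's
disease, while controlling for population structure. `svcohort` implements
this pipeline end to end for deletions, insertions and inversions of at
least 50 bp, together with a synthetic-cohort generator that provides ground
truth for every stage.

## What the package computes

**Call comparison and collapsing.** Two calls are compared by sequence
similarity `1 − editdist(a, b) / max(|a|, |b|)` over their event sequences
and by size similarity `min(ℓ_a, ℓ_b) / max(ℓ_a, ℓ_b)`. Cross-sample
collapsing is greedy star clustering in descending quality: a record joins
an existing seed when both similarities are ≥ 0.95 and the breakpoints are
within 1000 bp of the seed, so each cohort site is represented by its
maximal-quality member. Inversions are recognized at ingestion when
`sim(REF, revcomp(ALT)) ≥ 0.80` with both alleles ≥ 50 bp.

**Replicate-calibrated quality filtering.** Calls are classified as
consistent between technical replicates of one individual when both
similarities exceed 0.70; the quality threshold is then chosen as the score
t maximizing Youden's J(t) = P(qual ≥ t | consistent) − P(qual ≥ t |
inconsistent). On score mixtures resembling real data this lands at ≈ 50.

**Cohort QC and annotation.** Robust-Mahalanobis flagging of the 2% most
aberrant samples by per-type call counts, binomial-enrichment screening of
studies concentrating outliers, exact Hardy–Weinberg tests, site-frequency
and singleton summaries, known-SV catalog intersection (reciprocal overlap ≥
0.5 for DEL/INV; distance + size rules for INS) with allele-frequency
concordance (r²), and gene annotation with overlap / within-5-kbp /
intergenic classes.

**Association.** Genotype PCA after MAF > 1%, HWE and LD-pruning (r² > 0.1)
filters; per-ancestry logistic regression of case status on dosage with
sex, technical covariates and PCs 1–5, Wald tests with a score-test fallback
under separation, Bonferroni thresholds `0.05 / m`, and sample-size-weighted
Stouffer meta-analysis `z_meta = Σ√n_i z_i / √Σn_i`. Tag-SNP LD is estimated
by the two-locus EM algorithm on the 3×3 genotype table (r², D′) with
conditional models for signal independence. Rare (MAF < 1%) pathogenic SVs
are aggregated per gene and category and tested with a burden score test, a
variance-component (SKAT-type) test whose mixture-of-χ² null is evaluated by
moment matching, and their hybrid (burden + burden-adjusted SKAT combined by
Fisher's method), gated at cMAC ≥ 10 and reported with Benjamini–Hochberg
q-values.

## Worked example

```r
library(svcohort)
cfg <- simConfig(nPerPop = c(150, 150), nSites = 250,
                 causalEffects = data.frame(site = 1, or = 2.5))
cohort <- simulateCohort(cfg, seed = 42)
qc <- applyQualityFilter(cohort$calls, t = 50)
cc <- buildCohort(qc$passed, cohort$meta)
cc
s <- sfsSummary(cc)
s$type_composition
pc <- svPCA(cc, mafMin = 0.01, K = 5)
y <- as.numeric(sampleMeta(cc)$status == "case")
g <- as.numeric(dosageMatrix(cc)[1, ])   # the planted causal deletion
logisticAssoc(y, g, cbind(intercept = 1, pc$scores[, 1:2]))
```

prints

```
CohortCallset: 161 site(s) x 300 sample(s)
  DEL: 99  INS: 56  INV: 6  singletons: 30
  svtype  n   pct
1    DEL 99 61.49
2    INS 56 34.78
3    INV  6  3.73
   or_ ci_low ci_high      p
g 3.22  0.976    10.6 0.0549
```

The 11,357 raw calls lose 1,230 low-quality (mostly injected false) calls to
the threshold-50 filter and collapse to 161 polymorphic sites whose type mix
tracks the configured 56/42/2 DEL/INS/INV proportions. The planted odds
ratio of 2.5 at site 1 is estimated at 3.2 — with 300 samples the confidence
interval is wide, which is exactly why the package's calibration suites run
at n = 2000–6000.

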