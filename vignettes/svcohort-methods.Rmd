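---
title: "Methods: SV cohort harmonization and association in svcohort"
author: "svcohort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV cohort harmonization and association in svcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`svcohort` takes per-sample VCFs of sequence-resolved structural variants
(deletions, insertions, inversions; ≥ 50 bp; PASS filter) through collapsing,
quality control, annotation and case-control association. Internally a call
set is an `SVCallSet` wrapping a `GRanges` of reference spans; the collapsed
cohort is a `CohortCallset` extending `RangedSummarizedExperiment` with a
sites × samples dosage assay (0/1/2, `NA` for missing). Coordinates are
0-based half-open internally and 1-based in VCF I/O, with the leading shared
base included in REF/ALT — the standard VCF dialect. `svlen` is the absolute
allele-length difference for DEL/INS and the reference-span length for
inversions, whose two alleles have (nearly) equal length.

# Call comparison

Sequence similarity is defined as `1 − editdist(a, b) / max(|a|, |b|)`. The
measure is deterministic, symmetric, bounded in [0, 1] and checkable against
a dynamic-programming oracle, which is why it was chosen over
alignment-score variants whose parameters would themselves need fixing. The
compared sequences are the *event* sequences: the deleted bases for a DEL,
the inserted bases for an INS (so two insertions at the same anchor compare
their payloads, not their one-base REF), and the ALT allele for an INV.
`N` counts as an ordinary mismatching symbol. Size similarity is the
min/max length ratio. Two similarity regimes appear throughout:

* replicate concordance uses a **strict** conjunction, both similarities
  **> 0.70**;
* cross-sample collapsing and catalog-style matching use **≥ 0.95** within
  1000 bp of start distance, same type required.

The 1000 bp window is interpreted as *start*-distance (the alternative —
any-breakpoint distance — differs only for long events whose sizes already
fail the size gate).

Collapsing is greedy star clustering: records are processed in descending
quality (ties: chrom, start, record id — fully deterministic), each record
either joins the best-matching existing *seed* or founds a new site. Matching
against the seed rather than any member prevents transitive chaining, and
the surviving representative is automatically the maximal-quality member
("keep max qual" semantics). Identical allele strings short-circuit the
edit-distance DP, and a candidate whose allele-length difference alone
already caps similarity below the gate is skipped before the DP; both
shortcuts are exact.

# Replicate QC and the quality threshold

Calls matched one-to-one between two sequencing runs of the same individual
(all C(k,2) pairs when an individual has k > 2 replicates) with both
similarities > 0.70 are *consistent*; below-threshold and unmatched calls
are *inconsistent*, so every call is counted exactly once. The cohort
quality threshold is the grid score t maximizing Youden's
J(t) = P(consistent ≥ t) − P(inconsistent ≥ t), ties resolved to the
smallest t; a Kolmogorov–Smirnov mode (maximizing the absolute ECDF gap) is
available behind a flag and coincides with Youden's optimum whenever the
consistent distribution stochastically dominates. J was chosen because
"best segregates" is naturally a two-distribution separation criterion and
J's optimum for two equal-variance Gaussians is their midpoint, making the
calibration testable against a planted boundary. The quality score itself is
treated as an opaque monotone score, not assumed phred-scaled.

# Sample and study QC

Per-sample (DEL, INS, INV) counts are log1p-transformed and scored by a
robust Mahalanobis distance — median centre, Spearman correlation mapped to
the Pearson scale by 2·sin(πρ/6), MAD scales — and the top 2% of distances
are flagged. This deterministic rule replaces a trained one-class SVM with
the same flagged fraction: it has no fitted state, identical output on
identical input, and a planted-outlier recovery test. "A study concentrates
outliers" is formalized as a one-sided binomial tail test of the study's
outlier count against the global rate, BH-corrected, requiring at least two
outliers; all samples of implicated studies are dropped. Replicates are then
reduced to one sample per individual (highest call count) before cohort
construction. Missing genotypes are excluded from allele-frequency
denominators.

# Annotation

DEL/INV sites are annotated over their full reference span; insertions by
their single anchor base. Site classes (gene overlap, proximal within
5 kbp, intergenic) are mutually exclusive and exhaustive. Feature lists add
`intron` when part of the within-gene overlap is not covered by the gene's
exons. Catalog matching uses reciprocal overlap ≥ 0.5 for DEL/INV
(configurable; the catalog tools this mirrors do not publish a single
value) and, for insertions, anchor distance ≤ 1000 bp with a relaxed size
similarity of 0.5, because catalog insertion lengths are often approximate.
One representative transcript per gene is assumed in the gene models.

# Population structure

Two-locus LD uses the composite EM on the 3×3 dosage table (tolerance 1e-8,
≤ 1000 iterations), resolving double-heterozygote phase; r² and D′ come from
the converged haplotype frequencies. PCA filters sites to MAF > 1% and exact
HWE p above 0.05/m (m = MAF-passing sites), LD-prunes at r² > 0.1
(sliding window of 50 sites, step 5 — conventional values), centres dosages
at 2p̂, scales by √(2p̂(1−p̂)), mean-imputes missing values, and takes a
truncated SVD with a deterministic sign convention (largest-magnitude
loading positive). Relatedness-aware PC extraction is *not* implemented;
plain PCA is valid for the generator's unrelated samples, and association
models use fixed-effect PC adjustment rather than a random-effect
relatedness term for the same reason. Each PC is screened against batch
labels by a Kruskal–Wallis test plus a complete-separation flag (disjoint
score ranges), since a batch-separating PC must be treated as a technical
axis, not an ancestry covariate.

# Association

Single-variant tests are maximum-likelihood logistic regressions (IRLS,
tolerance 1e-10, ≤ 50 iterations) of case status on dosage with covariates;
Wald z and two-sided p are primary, and quasi-complete separation
(non-convergence, |β| > 15, or exploding SE) falls back to the score test in
the covariate-only null model with a flag — deterministic behaviour on
degenerate rare-variant inputs. Conditional tests append the conditioning
dosage to the covariates. The tag-SNP scan reports pairs with EM r²
strictly > 0.4; haplotype placement calls the SV *same*/*opposite* to the
risk allele by the sign of D with |D′| > 0.5 — a formalization of a
qualitative judgement, and configurable. Meta-analysis is Stouffer's method
with √n weights on signed z.

Gene-based tests weight rare (MAF < 1%) members by Beta(MAF; 1, 25) by
default, with a literal-MAF mode provided because tools in this family
document either convention; both modes are tested, neither is asserted as
uniquely correct. The burden statistic is the score test of the weighted
dosage sum; the SKAT-type statistic Q = Σ w_j² S_j² is referred to its
mixture-of-χ² null via Liu-type four-moment matching, validated against a
100,000-draw Monte-Carlo mixture oracle (agreement within 10% relative
error in the tested range; moment matching avoids a characteristic-function
integrator at the cost of mild tail approximation). The hybrid combines the
burden p with a SKAT test on burden-orthogonalized genotype columns
(orthogonalized in the null-model metric, making the two statistics
asymptotically independent) through Fisher's method with 4 df. Sets require
cMAC ≥ 10; the null model is fit once per phenotype/covariate configuration
and reused across sets. Conditional set tests append the SNV/INDEL burden to
the covariates and re-test the SV-only set.

# The synthetic cohort generator

The generator emulates the *structure* of a multi-study WGS SV cohort, not
its scale: Balding–Nichols per-population allele frequencies
Beta(p(1−F)/F, (1−p)(1−F)/F) over a Beta(0.2, 2) ancestral spectrum
(right-skewed, most sites rare); a DEL/INS/INV mix of 55.8/41.8/2.4%; sizes
dominated by the 50–100 bp band with a Normal(300, 30) ALU-like mode and a
log-uniform body to 8 kbp; true-call qualities Normal(70, 10) against
false-call qualities Normal(30, 10), so the optimal separation sits at 50;
replicates with 5% dropout, Normal(0, 3) breakpoint jitter and 0.5% per-base
sequence error; case status from a logistic model with configured per-site
odds ratios plus sex and centre effects, intercept tuned to the target case
fraction. Sites are spaced 15 kb apart so distinct sites never co-collapse.
Tagged loci are built from two-locus haplotype frequencies solving
D = ±√(r² p_A q_A p_B q_B), with an explicit feasibility error naming the
maximum attainable r². Everything is reproducible from (config, seed).

What the generator does **not** emulate: genome-wide LD beyond the planted
pairs, mosaic ancestry/admixture, caller-specific breakpoint biases,
genotype-quality correlation with depth, and relatedness. Passing tests
therefore demonstrate algorithmic correctness and statistical calibration
under the stated model, not robustness to every artefact of real WGS call
sets.

# Validation sizes and numerical choices

The test and acceptance suites run at sizes chosen to make their statistical
assertions sharp while remaining desk-scale: type-I error of the
single-variant test over 2000 null replicates at n = 2000 (binomial band
0.041–0.060 at α = 0.05); burden/SKAT/hybrid calibration over 2000
replicates at n = 1000 under a fixed null model (score tests condition on
the null fit, so only genotypes are redrawn); planted odds-ratio 3.0
recovery at carrier frequency 0.013, n = 6000, median over 200 replicates;
tag-LD r² = 0.97 at n = 6000 (±0.03); and a two-population Fst = 0.1 split
(200 + 200 samples, 2000 sites) separated on PC1 with silhouette > 0.5.
HWE exact p-values are compared to a full-enumeration oracle to 1e-12 for
n ≤ 20. Degenerate inputs are handled deterministically: monomorphic loci
are errors where r² is undefined, constant burdens return p = 1 with a
flag, rank-0 SKAT kernels return p = 1, and p-values at machine bounds are
clipped with a warning before normal-quantile transforms.

# Known limitations

* No relatedness handling (GRM or PC-AiR style); results assume unrelated
  samples.
* Truvari-style matching is reimplemented from its published definitions,
  not guaranteed to reproduce that tool's internal scoring byte-for-byte.
* Duplication and translocation classes are out of scope; DUP↔INS ambiguity
  is not resolved.
* The Liu-type mixture approximation is least accurate in the far tail;
  p-values below ~1e-6 from the SKAT component should be read as orders of
  magnitude.
* The pipeline's interfaces are R functions (`runPipeline()` and the stage
  functions); there is no shell executable.
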