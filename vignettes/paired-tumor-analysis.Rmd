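---
title: "Methods: paired primary/recurrence tumor genomics with gliomaPairs"
author: "gliomaPairs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired primary/recurrence tumor genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaPairs)
```

# Scope and model

`gliomaPairs` analyzes paired tumor samples — one taken at diagnosis
("primary"), one at relapse or autopsy ("recurrence") — from the same
patient, with pediatric high-grade glioma (pHGG) as the motivating disease.
Five analysis stages are provided, plus a synthetic cohort generator that
plants known ground truth so every stage is testable without patient-level
sequencing data (which studies of this kind typically cannot deposit):

1. **Multi-caller somatic variant consensus and filtering**
   (`readCallerVcfs`, `buildConsensus`, `runFilterCascade`);
2. **Temporal partitioning and molecular grouping**
   (`partitionPair`, `assignGroup`, `conservationMatrix`);
3. **Allelic-imbalance (AI) detection from B-allele frequencies**
   (`selectHetSites`, `detectAI`, `compareAIRegions`);
4. **Joint coverage + BAF copy-number calling**
   (`normalizeCoverage`, `segmentLog2`, `unionSegments`, `classifyEvent`,
   `armLevelCalls`, `callCNV`);
5. **Methylation subgroup clustering**
   (`filterProbes`, `selectTopVariable`, `clusterSamples`,
   `pairCoClustering`), with cohort summaries in `summarizeClinical`,
   `burdenTable` and `compareBurdens`.

# The variant filter cascade

Somatic calling follows a consensus-then-filter design. A variant, keyed by
the exact `(chrom, pos, ref, alt)` strings, must be reported by at least 2
of 3 callers; the caller with the greatest depth contributes the
representative read counts (a deterministic choice that favors the
best-covered evidence). The representative mutant allele frequency (MAF,
`alt_reads / depth`) must reach 10%.

MAF filtering is two-tiered: genes of interest (`H3F3A`, `TP53`, `ATRX`,
`ZMYND11`, `LZTR1`) pass at MAF ≥ 5% (inclusive), all other genes at
MAF > 15% (exclusive). The asymmetric bounds follow the wording of the
thresholds they implement ("minimum of 5% … or greater" versus "> 15%").
Because a 10% read-support rule would nullify the relaxed 5% tier, the
default policy (`goiReadSupportExempt = TRUE`) waives read support for
genes of interest; setting it to `FALSE` applies the rule uniformly, so
both interpretations are available.

With a matched normal, a variant is **somatic** only when the normal shows
zero alt reads; 1 alt read (below `normalReviewThreshold = 2`) yields
**review_flagged** — the original analysis resolved such sites by manual
alignment inspection, which a pipeline cannot automate, so they are
reported but marked. Without a normal, known polymorphisms are removed at
population AF ≥ 5e-4 (1000 Genomes / EVS) or ≥ 5e-5 (ExAC); absent
population AF is treated as 0 (a novel variant, which is what these
filters intend to keep). Survivors are **putative_somatic** only when in
COSMIC or of high/medium functional impact.

Each rule reads only its own fields, so the final status is independent of
rule order (tested by property). Raising any threshold can only shrink the
retained set (monotonicity, also tested).

# Temporal partitioning and molecular groups

Partitioning is exact set algebra on variant keys: shared = intersection,
private = set differences; the three sets are a disjoint cover of the pair's
variant universe. Grouping uses driver annotations: a pair is
*H3/IDH1 mutant* given any of H3F3A K27M/G34V/G34R, HIST1H3B K27M or an
IDH1 codon-132 substitution in either tumor; else *NF1 germline* given a
germline truncating NF1 variant; else *H3/IDH1 wildtype*. Precedence
(H3/IDH1 > NF1 > wildtype) makes the residual category well defined; a
conflict is resolved by precedence and messaged. Driver matching uses
normalized protein-change tokens ("K27M") from the annotation input — no
transcript arithmetic is attempted. The gene-level conservation matrix uses
a curated, editable gene-to-pathway map (`inst/extdata/pathway_map.tsv`);
pathway rows are "any member gene altered". Gene-level sharing (same gene
in both tumors) is deliberately separate from variant-level sharing
(identical variant key), since "the same gene, a different mutation" is a
distinct biological statement.

`pairedTTest` implements the paired statistic from first principles
(`t = mean(d) / (sd(d)/sqrt(n))`, sample sd, `df = n - 1`, two-sided p) and
is cross-checked in the test suite against `stats::t.test` and against a
brute-force oracle whose p-value comes from numerically integrating the t
density; agreement is required to 1e-10. Zero-variance differences are an
error, not a silent NaN.

# Allelic imbalance

At a heterozygous site of depth $d$, the balanced-allele null makes the
B-allele frequency $\mathrm{Binomial}(d, 0.5)/d$, so
$z = (\mathrm{baf} - 0.5)\cdot 2\sqrt{d}$ is approximately standard normal.
`detectAI` divides each chromosome arm's sites into non-overlapping windows
of at least `window = 25` consecutive sites (an arm's sites are split into
`floor(n/window)` equal chunks, so no site is discarded — important on
small arms), computes the score $T = \sum z_i^2$ per window, and refers it
to the upper tail of $\chi^2_{n_\mathrm{window}}$. Benjamini–Hochberg
correction is applied across all windows of a sample at `alpha = 0.05`;
runs of adjacent significant windows merge into maximal segments trimmed to
their first/last site.

Two design points deserve emphasis:

* **The statistic is self-contained per window.** An earlier candidate —
  ranking a window's folded deviations against the rest of the genome —
  is exchangeable under the null but loses *all* power when imbalance is
  genome-wide, a case that actually occurs (whole-genome copy-neutral LOH
  after radiotherapy). The score test has no reference to contaminate.
* **An effect-size floor** (`minDev = 0.1` mean folded deviation) keeps
  borderline noise windows out when overwhelmingly significant windows
  elsewhere relax the BH cut. The floor sits well above binomial noise at
  the depths considered (≈ 0.04 at 100×) and below the ≈ 0.15 deviation of
  a single-copy event at 60% aberrant-cell fraction, so events detectable
  at realistic purity are unaffected.

Folding (squaring) makes all results invariant under the allele
relabelling `baf → 1 − baf`, which is tested. Sharing of AI regions
between primary and recurrence is any-overlap (≥ 1 bp, same chromosome)
and counted per list regardless of region size, so a region split across
two partner regions contributes asymmetric shared counts — both are
reported.

# Joint coverage + BAF copy-number calling

Coverage is binned (`binSize` sites per bin), each sample median-scaled
(median, not mean, to resist focal events), and log2 tumor/normal ratios
segmented by recursive binary segmentation: split at the maximal
two-sample t statistic, accept while $|t|$ exceeds `tThreshold = 5`,
minimum 5 bins per segment. This is simpler than full circular binary
segmentation and is adequate for the large events targeted here; the
threshold of 5 comfortably separates a one-copy step from the maximal
spurious t on a few hundred null bins.

Event classes come from the two feature states: gain (mean log2 ≥ +0.3) is
**amplification**, loss (≤ −0.3) **deletion**, coverage-neutral imbalance
**copy-neutral LOH**, neutral-and-balanced none. The ±0.3 defaults detect
single-copy events at purity ≥ 0.6 (a one-copy loss at purity $p$ gives
$\log_2(1 - p/2)$, ≈ −0.51 at $p = 0.6$).

The two features' segments are combined by a breakpoint-union partition.
Since coverage bins and AI windows estimate the same underlying breakpoint
at different resolutions, boundaries closer than `snapDistance` are
clustered to their median first — by default 1.5 AI windows of median
marker spacing, the positional uncertainty of an AI boundary. Each cell
takes its coverage state by maximal overlap and is imbalanced when AI
segments cover ≥ 50% of it. Without snapping, edge slivers
(neutral-coverage + imbalance) masquerade as cnLOH at every amp/del
boundary; this was the dominant error mode in validation. An arm-level
event is emitted when one class covers ≥ 70% (`minFraction`) of the arm's
cell-covered bases.

GC correction is omitted (the synthetic tracks carry no GC bias) and is a
known limitation for real data, as is the absence of tumor purity/ploidy
estimation.

# Methylation clustering

Probes on chrX/chrY, SNP-overlapping probes and cross-reactive probes are
removed; the 3000 most variable probes by sample standard deviation
(n−1 denominator; ties broken lexicographically by probe id, so selection
is deterministic) feed average-linkage hierarchical clustering on
correlation distance $1 - r$. "Pearson rank correlation" in the
literature this models is ambiguous between Pearson and Spearman; the
default is Pearson on beta values — "Pearson" being the operative word and
betas bounded continuous — with `method = "spearman"` available. Flat
labels are cut at `k = 4`, the number of methylation subgroups these
cohorts exhibit (K27M, G34R/V, IDH1, wildtype); a pair co-clusters when
both members share a flat label. Pairs with one clustered member are
skipped with a message, mirroring cohorts where one member's array fails
QC.

# The synthetic cohort generator

`simulateCohort` emulates the study conditions of a 16-pair pHGG cohort:
group fractions 7/16, 7/16, 2/16 (H3/IDH1 mutant / wildtype / NF1
germline); mean exome depth 69×, the cohort-wide average reported for this
kind of study; tumor purity 0.8 (plausible for resected HGG; per-sample
purity is not reported in such studies, so one value is fixed); shared
passengers fully clonal and private passengers at cancer-cell fraction
0.8. Read support is binomial thinning:
`alt ~ Binomial(depth, purity × clonal_fraction / 2)` — the simplest model
that reproduces the MAF behavior the filters act on. Caller sensitivity is
0.95 per caller with 2 expected false positives per sample per caller,
drawn uniformly over the genome at MAF below ~0.12 to exercise the MAF
filter; germline variants appear at BAF 0.5 in tumor and normal to
exercise the zero-alt-in-normal rule, with 30% marked as known
polymorphisms to exercise the population filters.

Driver biology follows the cohort's co-occurrence rules: every H3/IDH1
driver is clonal, shared, and partnered (TP53, or ACVR1 with the histone
3.1 K27M); NF1-germline pairs carry a germline truncating NF1 variant and
acquire 17q copy-neutral LOH at recurrence; a configurable hypermutator
pair multiplies passenger counts (default ×10). Structural events plant
BAF centers 0.2/0.8 for single-copy changes (typical of 60–100%
aberrant-cell fraction — detectable but not trivial) and coverage
multipliers $(2 \pm p)/2$. Methylation is simulated as probe baselines
plus a +0.3 beta shift on subgroup signature probes, pair-level noise
(sd 0.02) and probe noise (sd 0.05).

What the generator does **not** emulate — and what green tests therefore do
not certify on real data: mutational signatures (e.g. temozolomide),
subclonal phylogenies beyond the shared/private dichotomy, GC and
FFPE-quality artifacts, read-level alignment error, and array batch
effects. Identical configurations and seeds produce byte-identical run
directories; every run writes a manifest with a configuration hash.

# Numerical choices and problem sizes

Default problem sizes in the test suite and the acceptance script are desk
scale, chosen to probe each method at realistic marker densities: AI
recovery uses 100 seeded simulations of 700 heterozygous sites on one
chromosome at depth 85 with two planted segments (≈ 45 and ≈ 112 sites);
CNV recovery uses 100 simulations of 3000 sites over three chromosomes
(one planted event per class, several hundred coverage bins each); the
genome-wide cnLOH scenario uses 6000 sites over all 22 autosomes; the
methylation property uses a full 16-pair cohort with 8000 probes.
Recovery is scored by ≥ 50% overlap-fraction matching between called and
planted events.

Degenerate inputs are handled explicitly rather than silently: zero-variance
paired differences, zero-variance beta samples (error naming the sample),
arms with fewer sites than one window (no call), all-flagged probe sets
(empty matrix, downstream error), and VCF records without usable AD/DP
(skipped with a warning).

# Known limitations

Variant keying is exact string matching without indel left-alignment —
safe for the generator's normalized output, not guaranteed for arbitrary
real VCFs. The AI caller assumes site-level binomial noise; overdispersed
real data would need a beta-binomial null. Arm boundaries are fixed to the
bundled GRCh37 table. The methylation module consumes normalized beta
values; array preprocessing and classifier-based subgroup assignment
against a reference cohort are out of scope.
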