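---
title: "Methods: cross-tissue methylome comparison, covariation, and obesity EWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue methylome comparison, covariation, and obesity EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmeth)
```

This vignette documents the statistical procedures the package implements,
the assumptions behind them, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical conventions that matter at decision boundaries.

## Data model and assumptions

All analyses operate on beta values — methylation proportions in [0, 1],
"% DNA methylation" when multiplied by 100 — in probe-by-sample matrices,
with the two tissues of each individual profiled on the same array design.
Working on the beta scale keeps every effect directly interpretable as a
methylation-percentage difference; the cost is that measurement noise is
truncated at the boundaries, which the generator reproduces deliberately
(truncated-normal noise, clipped to [0, 1], rather than logit-normal). Near
0 or 1 this makes per-site test statistics mildly non-normal; the
calibration checks in the test suite quantify how small that effect is at
the cohort sizes used.

## Quality control and normalization

* **Probe filters.** A probe is dropped when its detection p-value exceeds
  0.05 in more than 5% of samples, when its bead count falls below 3 in at
  least 5% of samples, or when it appears on a user-supplied exclusion list
  (SNP-proximal probes within 10 bp of the CpG, cross-reactive probes).
  Filters are applied in the fixed order detection-p → beads → exclusion
  lists so per-stage counts are reproducible; the retained set itself is
  order-independent because a probe is removed iff it fails *any* rule. The
  bead rule's sample fraction is a design choice (the ≥ 5% convention
  mirrors the detection-p rule); it is recorded in the `qc_report`.
* **Sample outliers.** Samples are flagged on principal-component scores by
  two rules — PC1 outside median ± 2 × IQR, and Euclidean distance of the
  (PC1, PC2) score from its coordinate-wise median beyond 5 MADs — combined
  by intersection by default (both must agree), configurable to union or
  either rule alone. The MAD rule is this package's robust replacement for
  high-dimensional outlier machinery: rotation-invariant in the leading
  score plane, and deterministic.
* **Normalization.** Between-sample quantile normalization is applied
  separately within the Infinium type I and type II probe strata
  (`limma::normalizeQuantiles`). This keeps the two chemistries' different
  dynamic ranges from contaminating each other while forcing identical
  per-stratum value profiles across samples. It is a beta-scale
  re-specification of intensity-based type-stratified normalization: the
  key property preserved is type-wise between-array harmonisation; the
  background-equalisation step that needs raw intensities is out of scope.
* **Identity checks.** The array's non-CpG SNP probes read genotype; matched
  samples must correlate at r ≥ 0.9 across them. Constant SNP vectors give
  an "indeterminate" verdict rather than a pass.

## Methylome characterization

Sites are categorized by cross-sample median beta: low < 0.20,
high > 0.80, intermediate otherwise (boundaries fall into intermediate;
medians interpolate between order statistics, R type 7 — documented because
category membership is threshold-sensitive). Region enrichments are
two-sided Fisher exact tests of (in region vs not) × (extreme category vs
intermediate background). The imprint band 0.40–0.60 is a separate named
threshold: imprinted loci carry parent-of-origin allele-specific
methylation, so somatic tissue sits near 50% while gametes sit at 0% or
100%; enrichment of the band is tested per imprint class and tissue against
the array-wide background. Reported Fisher p-values are floored at 1e-50
(`p_report`), with raw values retained. Genomic-interval overlap treats
probe positions as 1-based and intervals as 0-based half-open BED: position
p overlaps [s, e) iff s ≤ p − 1 < e, the same convention GenomicRanges
applies after BED import.

## Paired differential methylation

Site-wise tissue differences use a plain paired t-test on sperm − blood
differences (no variance moderation — with ~47–90 pairs the per-site t-test
is adequately powered and keeps the statistic exactly as specified), with
pairwise-complete pairs per probe, n − 1 degrees of freedom, and the
EPIC-scale significance threshold 9e-8. Probes with fewer than 4 complete
pairs report `p = NA` and never count as significant. Region-wise
comparisons pair each probe's two tissue medians and t-test them across the
probes of a region. Replication concordance is the Pearson correlation of
per-probe effects across cohorts.

## Cross-tissue covariation

* **Variability filter.** Only sites whose middle-80% sample range (10th to
  90th percentile, linear interpolation, inclusive ≥) is at least 0.05 beta
  in *both* tissues are tested, so single outliers cannot manufacture
  correlations at flat probes.
* **Correlation and null.** Pearson r per site across matched individuals;
  p from the t transform on n − 2 df; threshold 9e-8. The permutation null
  re-pairs blood and sperm samples by a uniform random permutation per
  round (100 rounds by default) and pools r across rounds and sites. The
  pooled Fisher-z SD closes on 1/√(n − 3), which the acceptance checks
  verify; an empirical-quantile summary of the pooled null is reported as an
  extension beyond the purely visual overlay.
* **Modality, method 1 (clustering).** For each significant site, the paired
  (blood, sperm) points are screened for outliers by a generalized-ESD
  (Rosner) test on Euclidean distances from the coordinate-wise median (up
  to ceiling(0.1 n) outliers at alpha 0.05) — the simplest
  rotation-invariant reduction of the one-dimensional test to 2-D. Sites
  are then clustered at k = 2 and 3 (k-medoids by default for robustness;
  k-means available), k chosen by average silhouette width. A winning
  solution whose between- to within-cluster sum-of-squares ratio is below 2
  has its cluster count decremented (k = 2 decrements to a unimodal call):
  this deterministic rule automates what would otherwise be a manual
  reassignment of weakly separated solutions, using the ratio-below-2
  trigger itself as the criterion. A multi-cluster call is *outlier-driven*
  when its smallest cluster holds at most max(1, 0.05 n) points or when
  every minority cluster consists solely of ESD-flagged points — at n ≈ 47
  this reproduces "driven by single outliers" behaviour while remaining
  configurable. The ESD screen also serves its exclusion role: no flagged
  outliers plus a sub-threshold variance ratio yields a unimodal call.
* **Modality, method 2 (gap hunting).** Per tissue, sorted beta values are
  split wherever consecutive values differ by more than 0.05; the group
  count (capped at "trimodal" for ≥ 3, with the count retained) is the
  modality call and small groups flag outlier-driven sites. This is the
  one-dimensional counterpart the clustering method is cross-checked
  against.
* **Genetic annotation.** For each probe, the nearest-SNP distance is
  min |offset| over the SNPs in its probe sequence. Type II probes read the
  CpG dinucleotide at offsets 0/1 (which covers their extension base), so
  distance ≤ 1 is `cpg_site`; type I probes read the CpG at offset 0 and
  extend at offset −1 (`single_base_extension`). The type II convention for
  the extension position is a documented choice, not asserted as universal.
  CorSIV/mQTL-style enrichments are Fisher tests of correlated versus
  non-correlated variable probes, first restricting both sets to probes on
  which the flag is defined (e.g. the 450K-present subset) when the
  annotation derives from a smaller array.

## Obesity EWAS

Three designs, all with lean = 0 reference so positive effects mean higher
methylation in obese men:

1. **Single tissue:** per-probe OLS of methylation on the obesity indicator
   (or continuous BMI for comparisons against prior studies) plus
   covariates; in blood, estimated cell fractions enter with one of the six
   types dropped, the standard remedy for the sum-to-one collinearity.
2. **Cross tissue:** `methylation ~ tissue + age + batch + obesity +
   (1 | individual)`, REML, Wald test with Satterthwaite degrees of freedom
   — the conventional choice, and it matters near the 9e-8 boundary. For
   the balanced matched design (every individual once per tissue,
   covariates constant within individual) the fit decomposes exactly: pair
   differences estimate the tissue effect and residual variance, pair means
   estimate the between-individual effects with variance tau² + sigma²/2,
   and the obesity Wald t equals the between-stratum OLS t on n − p df.
   The package uses this decomposition as a vectorized fast path (50,000
   probes in ~2 s) and per-probe `lmerTest` as the general route; the test
   suite asserts their agreement (estimates to 1e-15, SEs to 1e-10). A
   negative tau² estimate is a boundary fit and collapses to pooled OLS,
   exactly as lme4 behaves.
3. **Interaction:** per-probe OLS `blood ~ sperm * obesity + age + batch`;
   the reported effect is the interaction coefficient. For sites passing
   the threshold, a leave-one-out diagnostic reports the maximal change in
   the interaction t statistic when one pair is dropped — interactions
   carried by a single individual are thereby exposed. The diagnostic is
   restricted to significant sites because that is where the question
   arises, and it is configurable.

Prior-study comparison uses a two-sided Wilcoxon rank-sum test of the prior
probes' p-values against the rest (the rank test named in the underlying
methods; a figure legend elsewhere calls it a Fisher test — the rank-sum is
implemented) and Spearman correlation of effect sizes over the shared
probes, rank-based to absorb study-specific scale biases.

## Cell composition and clocks

Reference-based deconvolution solves, per sample, non-negative least
squares of the sample's betas on the cell-type reference profiles, then
rescales onto the simplex when the solution sums above 1 — a documented
simplification of the full quadratic-programming projection whose adequacy
is established by the round-trip criterion (six-type Dirichlet mixtures at
noise SD 0.02 recovered within 0.05 mean absolute error; measured ~0.004).

Clocks are sparse linear predictors over clock CpGs plus a transform:
identity, or the piecewise log-linear age transform
((1 + a)·exp(s) − 1 for s < 0, (1 + a)·s + a otherwise; continuous and
strictly increasing with value a at s = 0, a = 20 years by default).
Published coefficient sets are consumed as CSVs, never bundled — they are
external models — and all testing uses synthetic clocks built to invert
their own construction. Missing clock probes (up to 20%) are imputed at the
cohort mean beta of the available clock probes. Age acceleration is the OLS
residual of DNAm age on chronological age (plus cell fractions in blood;
sperm residuals adjust for chronological age only, since blood cell
composition has no sperm analogue), and acceleration is regressed on each
metabolic trait separately.

## The synthetic-data generator

`generate_cohort()` draws the cohort the analyses are designed around:
90 individuals (68 lean, 22 obese with BMI > 26) by default, matched blood
and sperm, with per-probe baselines drawn from tissue- and CpG-region-
specific low/intermediate/high mixtures chosen so the genome-wide profile
shows the field's known features — islands hypomethylated, sperm more
polarised than blood (roughly 31%/51% of sites low/high in sperm versus
26%/38% in blood on generated cohorts). Planted classes: SNP-bimodal and
-trimodal sites (Hardy–Weinberg genotypes at MAF 0.4, shared across
tissues; levels 0.10/0.90 and 0.05/0.50/0.95), negatively correlated sites
(dosage effect with opposite sign per tissue — the simplest mechanism for
anti-correlation), outlier-driven sites (one individual displaced 0.5 in
both tissues), imprinted sites (0.5 in blood, 0.02 in sperm),
obesity-associated sites (+0.02 beta in obese individuals, both tissues),
and null sites. Measurement noise is truncated-normal (SD 0.02 by default —
a free parameter, set to a value typical of array replicate variability on
the beta scale), plus a per-individual intercept shared across tissues
(SD 0.01): real cohorts have inter-individual variation, it is what the
mixed model's random effect absorbs, and it reproduces the slight rightward
shift of observed null correlations relative to the permutation null seen
in practice. Batch effects (SD 0.005 at 20% of probes, second batch) and
0.5% detection/bead failures give QC and the batch covariate real work.
MAF 0.4 keeps all three genotype classes present at n = 47 with probability
> 0.999, so trimodal sites are recoverable in principle.

What the generator does **not** emulate: raw two-channel intensities and
probe chemistry, dye bias, spatial artefacts, realistic linkage between
SNPs, age-dependent methylation drift at non-clock probes, or correlated
probe neighbourhoods. Passing tests therefore demonstrate statistical
correctness of each stage under a controlled, truthful data-generating
process — not robustness to every artefact of real arrays.

## Numerical conventions and degenerate inputs

Zero-variance paired differences yield t = 0, p = 1 when the mean
difference is zero (identical tissues) and |t| = ∞, p = 0 otherwise;
zero-variance probes give r = NA in correlation scans; constant traits give
NA slopes and an all-zero acceleration vector the slope 0, p = 1
convention. Exactly-boundary values follow strict inequalities for
categories (median exactly 0.20 is intermediate) and inclusive inequalities
for the variability filter (range exactly 0.05 is kept). Fisher odds ratios
use the sample cross-product, with an infinite sentinel when one off-cell
margin is zero. All generators and the permutation null are seeded and
bit-reproducible.

## Problem sizes and validation design

The validation suite runs oracle-equivalence checks (closed forms,
hypergeometric enumeration, normal equations, brute-force sort-and-split)
on small instances; type-I calibration on five null cohorts of 47 pairs ×
50,000 probes per model; planted-signal recovery at n = 47 (modality) and
n = 90 (obesity, noise SD 0.01 per the recovery scenario); a permutation
null at n = 40 with ≥ 10,000 pooled draws; and the deconvolution and clock
round trips at n = 50. These sizes give tight binomial bands (3 SDs at
50,000 probes is ±0.13 percentage points on the 5% rate) while the whole
suite completes in minutes.

One power figure deserves honesty: with a 0.02 obesity effect, noise SD
0.01 and intercept SD 0.01 at 68 + 22 individuals, the obesity effect is
purely between-individual, so the correct mixed-model test draws
information only from the 90 pair means; its exact theoretical power at
the 9e-8 threshold is 0.78 (noncentrality 6.66 against a critical t of
5.84 on 86 df), and the measured power matches. Only an analysis that
wrongly pools the 180 observations as independent would report more.

## Known limitations

Intensity-level preprocessing (idat parsing, background correction, dye
bias) is out of scope; inputs are betas. The modality procedure's cluster
count is capped at 3 by design (higher multimodality is reported via the
gap hunter's group count). The interaction scan's leave-one-out diagnostic
refits n models per significant probe and is therefore gated on
significance. Published clock coefficient sets must be supplied by the
user, and genome builds must already agree between probe annotation and
interval files — no liftover is performed.
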