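---
title: "Methods: sex-chromosome-aware methylation array processing"
author: "methylXY authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-chromosome-aware methylation array processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and design decisions
behind methylXY, in the spirit of the methods sections of mature
preprocessing packages. It states no empirical result that the test suite
or `scripts/acceptance.R` do not themselves compute.

## Why the sex chromosomes need their own workflow

Methylation arrays report, per CpG, methylated (M) and unmethylated (U)
fluorescence intensities, summarized as `β = M/(M+U+offset)`. Two
biological facts break autosomal processing conventions on the X and Y:

1. **Dosage.** XX samples carry no Y. Their chrY probes hybridize nothing
   and return background fluorescence in both channels, so β centres near
   0.5 with high detection p-values. Any per-probe statistic pooled across
   a mixed-sex cohort mixes real measurements (XY) with noise (XX).
2. **X-chromosome inactivation.** In XX cells one X is silenced; its
   CpG-island promoters gain methylation while the active X's stay low.
   The array averages both alleles, so XCI-subject promoters in XX samples
   read `(β_Xa + β_Xi)/2` — an intermediate value with no XY analogue.

The package therefore stratifies exactly the steps where pooling is
harmful (detection-p and non-variability filtering on chrY; all X/Y
statistical analysis), and deliberately does **not** stratify bead-count
filtering, where probe detectability is independent of hybridization
signal and stratification would only cost power.

## Elementary transforms

* Beta offset: 100 (the platform convention; configurable). The source
  analyses do not state their offset.
* M-values: `log2(β/(1-β))` with β clipped to `[0.001, 0.999]` so all
  values are finite; the clip is configurable. Linear modelling happens on
  M-values, effect sizes are reported on the beta scale.
* Detection p: `1 - Φ((M+U-μ_bg)/σ_bg)` against a per-sample Gaussian
  background summarized from negative-control probes, one pooled
  background per sample (channel-specific backgrounds differ between
  published implementations; ours is documented so users can substitute a
  precomputed detection-p matrix, which the data model accepts directly).

## Quality control

**Sex inference.** `nX` and `nY` are the per-sample median total
intensities over chrX/chrY probes divided by the autosomal median. The
default decision rule — XX if `nY < 0.3` and `nX > 0.8`; XY if `nY > 0.6`
and `nX < 0.65`; otherwise *anomaly* — uses thresholds chosen once to
bisect the simulator's cluster geometry (XX near (1, 0.1), XY near
(0.55, 1)) with ≥5σ margin; no thresholds are published for the original
workflow. Ambiguity is never silently resolved: intermediate intensities
(e.g. a 45,X/46,XX mosaic, which the simulator models as a convex
intensity mixture at a configurable cell fraction) always yield an anomaly
flag. A nearest-centroid mode is provided for real datasets whose clusters
sit elsewhere.

**Contamination.** Betas at the 65 rs genotyping probes are pooled across
all probes and samples and fit by EM with a four-component mixture: three
beta components (genotype clusters AA/AB/BB) plus a Uniform(0,1) outlier
component that absorbs the intermediate betas produced when two genomes
mix. Design choices:

* Initialization: shapes (1,20), (20,20), (20,1); weights (.3,.3,.3,.1).
  The fit is deterministic — no stochastic restarts — so no seed parameter
  exists.
* M-step: beta shapes are updated by *weighted maximum likelihood*
  (Nelder-Mead on log-shape parameters), accepted only when they improve
  the weighted likelihood. This makes the procedure an ECM algorithm whose
  observed-data log-likelihood is provably non-decreasing — an invariant
  the test suite asserts on every trace. Method-of-moments updates, the
  obvious alternative, do not carry that guarantee.
* Score: `snp_outliers(s)` is the mean natural-log odds of outlier
  membership over sample *s*'s SNPs; samples above −4 are flagged (the
  published cutoff; the log base is not published, natural log is used and
  configurable in effect through the cutoff).
* Hard genotype calls require posterior > 0.9; duplicate detection reports
  pairs with ≥ 90% agreement over ≥ 10 jointly-called SNPs. Under
  Hardy-Weinberg at allele frequency 0.5, unrelated pairs agree at 37.5%
  in expectation, so the margin is wide. The joint-call floor matters:
  contaminated mixtures lose calls exactly at discordant SNPs, which would
  otherwise inflate agreement over the concordant remainder.

## Probe filtering

All exceedance comparisons are strict (`>`), and boundary cases (exactly
1% of samples failing) are tested at equality. Missing detection p-values
and bead counts count as failures (conservative; configurable by
preprocessing the matrices). Quantiles for the non-variability range use
R's default linear interpolation (type 7); the operational definition is
the 10th–90th centile range < 0.05, with the quantile pair configurable
(setting it to (0,1) reproduces a plain range). When an external
non-variable probe list is supplied, removal requires membership in
*both* the cohort-derived set and the list — the intersection is
commutative and never larger than either set. The exceedance fraction
defaults to 1%; a documented `"aca-reanalysis"` preset raises it to 5%,
the setting appropriate for small cohorts. Count denominators in the
report are cg/ch probes only; rs and control probes are tracked separately
and dropped before analysis.

## X/Y annotation

PAR1/PAR2/XTR coordinates (hg19, 1-based inclusive, both chromosomes) are
built in. BED input is converted on read and the conversion logged. Probe
footprints are approximated from manifest fields: 50 bases with the 3'
end at the interrogated cytosine (Infinium II) or at the adjacent
single-base-extension site (Infinium I), oriented by strand; the
`three_prime_zone` is the 5 footprint positions nearest the 3' end, where
underlying SNPs interfere most. This is an approximation to true probe
alignment (source sequences are out of scope) and a user-supplied
footprint table can replace it. Cancer-testis promoters default to
TSS−1500..TSS+500 on the gene strand — no promoter definition is published
for this use — and explicit promoter intervals may be supplied instead.
Interval overlap is delegated to GenomicRanges but verified in the test
suite against a per-base brute-force oracle on hundreds of random
instances. Region overlap for annotation uses the CpG position by default
(whole-footprint mode is available); which convention produced the
published XTR probe counts is not stated, and the package reports whatever
the supplied manifest yields.

## Harmonization evaluation

Concordance between two matrices (raw vs normalized, pre vs post batch
correction) is summarized per sample and chromosome context as Spearman ρ
(average ranks for ties) and RMSE over pairwise-complete probes, with chrY
rows computed for XY samples only. Both metrics are computed on the beta
scale, matching the published "beta values before versus after"
comparisons.

The batch adjustment is the canonical parametric empirical-Bayes
location/scale model: per-probe standardization against a design that
protects biological covariates, per-batch location (normal prior) and
scale (inverse-gamma prior) estimates shrunk with moment-matched
hyperparameters, then back-transformation. It operates on M-values in the
pipeline (the adjusted scale is not stated in the source; beta-scale
adjustment is possible by passing betas). A single-batch input is returned
unchanged — there is no batch effect to estimate. The non-parametric
variant is out of scope. Confounded designs (batch aliased with a
covariate) are rejected by rank analysis, naming the aliased columns.

The batch/sex balance check is an exact r×c independence test: full
enumeration of tables with the observed margins, summing the null
probability of every table at most as probable as the observed one
(two-sided, the same convention as `fisher.test`), with a seeded
Monte-Carlo fallback (tables drawn with fixed margins; SE attached) when
enumeration exceeds a workload budget. Cohort-demographics-sized 2×3
tables are well within exact range.

## Differential methylation and XCI

Per-CpG ordinary least squares on M-values, two-sided t-test on the
phenotype coefficient, BH step-up within each stratum × chromosome family
(X-in-XX, X-in-XY, Y-in-XY) — matching the convention of reporting X and Y
results separately. Plain OLS rather than empirical-Bayes variance
moderation is the default because the source workflow specifies only
"linear modelling"; moderation is a deliberate non-default. Δβ is the
difference of group mean betas, reference level minus the other level.
chrY may never be requested in the XX stratum (error, not warning).

XCI calls use mean promoter beta per gene: escape if both sex means
< 0.2; subject if the XY mean < 0.2 and the XX mean lies in [0.3, 0.7];
otherwise indeterminate. The thresholds are not published; the defaults
follow the promoter-hypomethylation convention (< 0.2) with the subject
band centred on the Xa/Xi average, and all are configurable.
Cancer-testis promoter probes are excluded when an annotation table is
supplied, since their promoter methylation is high in all tissues
regardless of XCI. Note an instructive interaction surfaced by the worked
example: escape-gene promoters are hypomethylated in both sexes and hence
nearly non-variable, so aggressive non-variability filtering can remove
the very CpGs an XCI analysis needs — run XCI calling on data filtered
with that in mind.

## The simulator: what it emulates, and what a green test establishes

The generator's defaults are the stated world of the test suite: 50 XX +
50 XY samples; 416 chrY probes of which 19% (79) are constant in XY — the
chrY census of the 450K platform and the published count of non-variable
chrY probes; 65 rs probes at allele frequency 0.5 (expected
unrelated-donor agreement 0.375); XCI-subject promoters at β_Xa = 0.05,
β_Xi = 0.85 (XX average 0.45) with 20% of X-linked genes escaping;
per-channel background ≈ 10% of foreground total, so XX samples show
nY ≈ 0.1 and chrY-in-XX betas ≈ 0.45 ("roughly 0.5") with high detection
p. Intensities are log-normal (foreground sdlog 0.15, background sdlog
0.2) with the X foreground halved in XY samples. Probe failure is a
per-probe property (1% of probes return background in every sample),
matching the semantics of a consistently failing probe and making
autosomal and XY-stratified chrY flag rates comparable binomial draws;
bead counts are Poisson (mean 14; 1% of probes mean 2.5), independent of
intensity, reflecting the finding that bead count is sex-independent.
Batch labels are assigned balanced within sex; the default batch *effect*
is zero because every evaluation states its own — the batch-correction
acceptance check injects per-probe shifts of 0.05 M-units (~1% beta at
midrange), the modest-cohort-effect regime in which pre/post distributions
remain highly correlated, which is precisely the premise of the finding it
mirrors.

What the simulator does **not** model: Infinium I vs II distributional
differences (type labels only), realistic genomic coordinate structure
beyond region consistency, cell-composition heterogeneity, and
correlated probe failure. A green suite therefore establishes the
*logic* of stratification, scoring and calling under a faithful
abstraction of the platform's signal model — not numerical agreement with
any specific real cohort, which would require the original IDAT-level
data.

Contamination is injected as convex intensity mixtures
`(1-f)·target + f·donor` in both channels with betas and detection p
recomputed, and spiked differential effects rewrite intensities so the
recomputed beta shifts by exactly Δβ (clipped shifts record their
effective value in the registry).

## Numerical choices and degenerate inputs

* All-zero intensities make sex normalization undefined → error, never NaN.
* Fewer than 2 complete pairs in a concordance cell → NA row plus warning.
* Degenerate contingency tables (a zero margin) → p = 1 with warning.
* EM non-convergence (bounded iterations) → warning with best-so-far fit.
* Empty post-filter datasets, rank-deficient designs, unknown sample or
  probe identifiers → errors naming the offenders.
* Seeds: the simulator requires one; pipeline reruns with the same seed
  are byte-identical, and the run manifest records seed, config digest and
  applied thresholds for audit.

## Known limitations

No IDAT parsing (matrices are consumed as delimited text; an adapter can
sit in front of `read_dataset`), no normalization algorithms (the package
evaluates pre/post matrices it is given), no DMR/co-methylated-region
discovery, no cell-composition deconvolution, no ancestry inference, and
no copy-number calling beyond the karyotype anomaly flag.
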