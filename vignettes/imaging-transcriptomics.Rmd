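---
title: "Linking regional gene expression to case-control brain maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking regional gene expression to case-control brain maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcortex)
```

## The analysis in one paragraph

`transcortex` implements a transcriptome–neuroimaging association analysis
for case-control studies of major depressive disorder (or any disorder with
regional brain measures). Subject-level regional measures — gray matter
volume (GMV) and the resting-state measures ALFF, fALFF and ReHo — are
turned into per-region case-control effect sizes (Cohen's *d*). The three
functional effect maps are summarised by their first principal component
(funcPC1); a region × gene expression atlas is summarised the same way
(genePC1). Each gene's regional expression profile is then screened against
funcPC1 and against the GMV *d* map with Spearman correlation, and genes
surviving Bonferroni correction are split by sign into four sets (funcPC1+,
funcPC1−, GMV+, GMV−). Transcriptional correlates are further related to
postmortem differential-gene-expression (DGE) betas through a bin-based
correlation estimator, and the selected sets are tested for
over-representation in user-supplied gene-set collections with Fisher's
exact test. A synthetic-data module generates every input with planted
ground truth so that the whole chain is testable without any external data.

## The statistical model, stage by stage

### Effect maps

For each region, a pooled-variance two-sample *t* statistic (case minus
control, `df = n1 + n2 - 2`) is computed on measures from which the
covariates — age, sex, education and head motion — have been regressed out
by OLS (fit on all subjects pooled; residuals are exactly orthogonal to the
design). The *t* statistics are converted to Cohen's *d* by the standard
two-sample relation

$$d = t \sqrt{1/n_1 + 1/n_2},$$

so *d* and *t* always agree in sign. Per-measure p values receive
Benjamini–Hochberg FDR correction at 0.05. The Student (pooled) form is the
default because "two-sample t-test" conventionally means the pooled test;
Welch's form is available via `welch = TRUE`.

### Principal-component summaries and their sign conventions

funcPC1 is the first PC of the regions × 3 matrix of functional *d* maps,
genePC1 the first PC of the regions × genes expression matrix; in both
cases columns are standardized (a configuration switch disables this for
the effect maps) and the component is extracted by SVD — a deterministic
solver, no randomized approximation. Scores are z-scored across regions.

PCA determines a component only up to sign, but directional claims
("expression is negatively associated with functional abnormality") need a
reproducible orientation, so both summaries fix it explicitly:

* **funcPC1** is flipped so that it correlates positively with the mean of
  the input maps. The three functional maps are strongly positively
  correlated in practice, so their mean is a stable reference.
* **genePC1** is flipped so that the sum of gene loadings is positive. The
  dominant spatial axis of a cortical expression atlas is carried by many
  genes loading coherently in the same direction, which makes the
  majority-loading orientation stable. (A tempting alternative — "correlate
  positively with the loading-weighted mean expression" — is vacuous: the
  scores *are* the loading-weighted expression, so that correlation is +1
  for either orientation.)

### Gene screening

Each gene's profile is correlated with the target map by Spearman's rank
correlation (average ranks on ties). Two-sided p values use the *t*
approximation $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; below 10 regions
(toy fixtures) the exact permutation null is used instead, where the
approximation is poor. Selection applies the Bonferroni threshold
$\alpha/G$ over the $G$ genes of one screen; each target map is its own
family (two maps are two separate analyses, reported as four signed sets),
matching how such screens are reported. Regions must match by name between
the expression matrix and the target map; mismatches raise an error rather
than being silently reordered.

### Bin-based DGE linkage

Postmortem DGE betas pile up near zero for most genes, which dilutes a
direct gene-level rank correlation with the transcriptional correlates. The
bin estimator ranks the common genes by transcriptional correlate
(descending; ties broken by gene id so the partition is deterministic),
splits them into `B` contiguous bins whose sizes differ by at most one
(the first `N mod B` bins take the extra gene), and correlates the per-bin
mean correlate with the per-bin mean beta. With `B = N` the estimator
collapses exactly to the direct gene-level Spearman correlation — a useful
identity that the tests check to machine precision. The default is
`B = 100` with a stability sweep over 50/150/200.

### Enrichment

Over-representation of a query set in an annotation set is the one-sided
hypergeometric tail on the 2×2 table, with the odds ratio `ad/bc`
(Haldane 0.5 continuity correction on zero cells, flagged, p unaffected).
The background defaults to the gene universe that entered the correlate
screen — selection happened inside that universe, so a genome-wide
background would overstate enrichment. BH correction is applied within each
query across the sets of one collection.

### Resting-state metrics

The metric module computes the three functional measures from
voxel-neighbourhood time series so the pipeline can start at time-series
level. ALFF is the sum of square-root periodogram amplitudes over
0.01–0.08 Hz of the linearly detrended series (no taper), per voxel, then
averaged over the block; fALFF divides by the full-spectrum amplitude sum
excluding DC, so it is scale-invariant and lies in [0, 1]. The sum (rather
than mean) over in-band bins is the default aggregation; both conventions
exist in the literature and differ only by a constant at fixed series
length, so `agg = "mean"` is exposed. ReHo is Kendall's coefficient of
concordance across the block's voxels,

$$W = \frac{12\sum_t (R_t - \bar R)^2}{V^2(T^3 - T) - V\sum_j T_j},$$

with the standard tie correction $T_j$; the implementation is cross-checked
against an independent reference implementation in the test suite. One
numerical caveat worth knowing: linear detrending of a finite window leaves
a small phase-dependent ramp residual, so even a pure in-band sinusoid can
show a few percent of spectral leakage; fALFF of in-band signal is
therefore close to, but not exactly, 1.

## The synthetic-data generator

The generator emulates the statistical structure of the study design, not
its imaging physics:

* **Expression.** A latent per-region gradient (z-scaled Gaussian) with a
  subset of "causal" genes loading on it; loadings are drawn with a
  positive mean so the atlas's first PC is a coherently oriented gradient,
  as in real cortical expression data; all other genes are independent
  noise.
* **Couplings.** A true difference map is tied to the gradient at a
  requested Spearman-scale strength via the Gaussian closed form
  $\rho_P = 2\sin(\pi\rho_S/6)$: mixing $\rho_P \cdot g$ with independent
  Gaussian noise yields exactly the requested population Spearman
  correlation. The $\rho_S = \pm 1$ limit is exact rank matching; the
  Gaussian mixture is the calibrated-noise mechanism in closed form.
* **Subjects.** Cases receive the true *d* map as a mean shift (in units of
  the residual sd, so the planted map is in Cohen's *d* units); covariates
  (age uniform 18–65 years, sex Bernoulli(0.5), education 6–22 years, head
  motion log-normal with median ≈ 0.14 mm) are drawn independently of
  group and enter additively, inflating variance without confounding.
  Site effects are not simulated, matching an analysis that adjusts for
  age/sex/education/motion only.
* **Functional measure structure.** The three functional maps share one
  latent map (true pairwise correlation 0.7) plus measure-specific noise;
  GMV has its own latent map.
* **DGE.** Betas are a coupling sign times the z-scaled true correlate plus
  heavy-tailed t(3) noise; a zero-inflation fraction (default 0.8) has its
  signal shrunk ×0.05, reproducing the near-zero pile-up that motivates the
  bin estimator. The shrinkage is applied to the signal term only — the
  noise floor is what buries the shrunk genes' ordering, which is exactly
  the regime where binning helps.
* **Probe samples.** Each gene is measured by several probes across one
  sample per donor-region; one planted representative probe tracks the
  gene's true profile with high cross-donor consistency, decoys track it
  weakly with large donor noise. Below-background probes are flagged above
  background in 30% of samples versus 95% for the rest, so the conventional
  50% filter separates them exactly.

All generators are pure functions of their parameters and seed: the global
RNG state is saved and restored around each call.

### Chosen scales, and why

Defaults were fixed once, before the downstream analyses were run in anger,
and define the simulated study conditions:

* `effect_sd_func = 0.15`, `effect_sd_gmv = 0.12` (sd across regions of the
  true *d* maps). The binding constraint is recoverability: the sampling
  error of Cohen's *d* is $\sqrt{1/n_1 + 1/n_2}$ — about 0.1 at 200 + 200
  subjects, *independent of the noise sd* — and a true-map spread far below
  it would attenuate any planted coupling beyond recognition, defeating the
  generator's purpose of providing recoverable ground truth. These values
  keep simulated effects in the weak regime reported for large case-control
  samples (|d| mostly < 0.3, GMV weaker than function) while leaving the
  planted couplings recoverable to within ±0.1 on the Spearman scale; they
  also put the observed pairwise correlations among the three functional
  effect maps in the 0.4–0.5 range and funcPC1's variance explained near
  0.65 at simulation scale, the empirical regime for such measures.
* `measure_cor = 0.7`: true shared fraction of the functional maps, picked
  so that the *observed* (estimation-noise-attenuated) map correlations
  land in the empirically reported band.
* Default couplings `rho_func = -0.3`, `rho_gmv = +0.35`: the sign
  structure of interest — expression negatively related to functional
  abnormality, positively to structural abnormality.
* Covariate betas (0.01/yr age, 0.2 sex, 0.02/yr education, 0.5/mm motion)
  produce covariate-induced variance comparable to a third of the residual
  sd — big enough that skipping residualization visibly attenuates effect
  sizes, small enough to be plausible nuisance.
* Simulation sizes used by the tests: 210 regions (a standard cortical
  parcellation count), 2 000 genes with 600 causal, 200 + 200 subjects, 100
  seeds for coupling recovery, 200 replicates for error control. These are
  the package's own choices of problem size for routine verification;
  generators accept the full-study sizes (≈ 15 000 genes, ≈ 800 + 800
  subjects) and the expression generator stays comfortably fast there.

### What the generator does *not* model

* **Spatial autocorrelation among regions.** Regions are exchangeable given
  the gradient; no smoothness-preserving null is available, and none is
  used by the analysis the package implements. Passing tests therefore say
  nothing about inference under spatially autocorrelated maps (spin-test
  style nulls would be the extension).
* **Site/scanner heterogeneity.** Multi-site intercepts are not simulated;
  the analysis regresses out four subject-level covariates only.
* **Realistic MRI volumes or donor anatomy.** The atlas builder starts from
  region-labelled probe samples; coordinate-to-parcel matching is out of
  scope.

Consequently, green tests demonstrate internal statistical correctness
(calibration, error control, estimator identities, recovery of planted
structure), not robustness to the spatial and batch structure of real
neuroimaging-transcriptomic data.

## Numerical choices and degenerate inputs

* PCA by SVD of the standardized matrix; constant columns are dropped with
  a warning (an error if fewer than two remain).
* Probe filter keeps probes whose above-background fraction is ≥ the
  threshold; the generator plants fractions (0.30/0.95) far from the 0.5
  boundary, so the boundary convention never matters in practice.
* Representative-probe ties (identical differential stability) break to the
  lexicographically smallest probe id; a single donor falls back to highest
  mean intensity with a warning.
* Bin partition puts remainder genes in the earliest bins; any consistent
  rule satisfies the collapse identity, this one is documented and tested.
* Zero-variance regions in the *t* stage, constant vectors in Spearman,
  empty gene-universe intersections, query genes outside the enrichment
  background, misaligned region names: all are errors naming the offender,
  never silent repairs.
* `|r_s| = 1` returns p = 0 by convention; BH q values are computed by the
  standard step-up with monotonicity enforcement.

## Design decisions that were genuinely open

* **Bonferroni family = one target map**, not both maps jointly: the four
  signed sets are reported per analysis, as is conventional for this kind
  of screen.
* **No site covariate** in the generator or the model: the emulated
  analysis adjusts for age, sex, education and motion only; a site
  intercept can be added for robustness experiments.
* **Hemisphere-specific probe selection** is not implemented; selection is
  global across samples. The within-hemisphere variant is not fully
  specified in the sources this design follows and the global rule is the
  simpler, testable choice.
* **ALFF aggregation**: sum over in-band bins (with `mean` exposed), since
  the two conventions differ by a constant for fixed series length.
* **Background universe for enrichment**: the screened gene universe, not
  the genome (selection bias lives inside the screen).
* **Subgroup analyses** (sex, age median split) are row filters on the
  subject tables (`subset` argument of `run_pipeline()`), re-running the
  effect stage on the subset; a covariate that becomes constant in a
  subgroup is dropped from the residualization design with a message.

## Known limitations

* Spearman p values for the mass screen rely on the *t* approximation at
  realistic region counts; it is accurate there, but the far-tail behaviour
  below ~20 regions is approximate (the exact path covers < 10).
* The variance explained by genePC1 on synthetic data (~20%) is in the
  right range for a real atlas, but the generator's single-gradient
  low-rank structure is a deliberate simplification; real atlases carry
  several correlated gradients.
* Enrichment assumes independent gene membership; co-expression-aware nulls
  are out of scope.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, output_dir = "run1")
res$gene_pc1_vs_func_pc1 # headline association, negative by construction
res$truth_report         # planted vs recovered couplings
```

The bundle written to `run1/` contains every stage table as TSV, the
selected gene sets as GMT, ground truth and PC metadata as JSON, and a
manifest of file MD5s: re-running the same configuration reproduces the
files byte for byte.
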