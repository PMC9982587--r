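# transcortex

Transcriptome–neuroimaging association analysis for case-control brain
maps.

## What problem this solves, and for whom

Large case-control neuroimaging studies of major depressive disorder
produce per-region abnormality maps — Cohen's *d* for gray matter volume
(GMV) and for resting-state functional measures (ALFF, fALFF, ReHo) — and a
natural question is whether the cortical distribution of gene expression
tracks those maps. `transcortex` is for researchers who want to run that
analysis end to end, reproducibly, from plain TSV inputs:

1. **Effect maps.** Per region, covariates (age, sex, education, head
   motion) are regressed out, a pooled two-sample *t* is computed (case −
   control), converted to Cohen's *d* via `d = t·√(1/n₁ + 1/n₂)`, with
   Benjamini–Hochberg FDR flags.
2. **PC summaries.** funcPC1 = first principal component of the three
   functional *d* maps across regions; genePC1 = first PC of the
   region × gene expression matrix (SVD, standardized columns, explicit
   sign conventions). The headline quantities are the Spearman correlations
   of genePC1 with funcPC1 and with the GMV *d* map.
3. **Gene screening.** Every gene's regional profile is correlated with
   each target map (Spearman, two-sided p from the *t* approximation);
   genes surviving the Bonferroni threshold α/G are split by sign into
   funcPC1+/funcPC1−/GMV+/GMV− sets.
4. **DGE linkage.** Transcriptional correlates are related to postmortem
   differential-expression betas directly and through a bin-based
   estimator: genes ranked by correlate, split into B ≈ 100 contiguous
   bins, Spearman over bin means (with B = N this collapses exactly to the
   direct correlation). Top-K up/down-regulated sets are derived from the
   betas.
5. **Enrichment.** One-sided hypergeometric (Fisher) over-representation of
   the selected sets in GMT collections, BH-corrected within collection,
   background = the screened gene universe.

A first-class synthetic-data module (`gen_expression`, `gen_subjects`,
`gen_probe_samples`, `gen_dge`, `gen_timeseries`) generates every input
with planted ground truth — a latent expression gradient, Spearman-scale
couplings between that gradient and the true difference maps, planted
representative probes, zero-inflated DGE — so the whole chain is testable
without access-restricted data. An expression-atlas builder
(`filter_probes`, `select_representative_probe`, `aggregate_to_regions`)
turns multi-donor probe-level samples into the region × gene matrix, and a
metrics module (`alff`, `falff`, `reho`) computes the functional measures
from time series (ReHo is Kendall's W with tie correction).

## Worked example

```r
library(transcortex)
cfg <- pipeline_config(seed = 7)   # synthetic mode, default study conditions
res <- run_pipeline(cfg)
```

The default configuration simulates 210 cortical regions, 2 000 genes (600
loading on a latent gradient), 200 + 200 subjects, planted couplings
rho_func = −0.3 and rho_gmv = +0.35, and 80% zero-inflated MDD DGE betas
negatively coupled to the functional correlates. The run above prints:

```
> res$func_pc1
PC1 summary: 210 observations, 65.8% variance explained (positive correlation with mean input map)
> res$gene_pc1
PC1 summary: 210 observations, 22.1% variance explained (positive loading sum)

genePC1 ~ funcPC1: r_s = -0.273, p = 5.94e-05
genePC1 ~ GMV d:   r_s = 0.281, p = 3.70e-05
selected genes: funcPC1+ 0, funcPC1- 74, GMV+ 76, GMV- 0
MDD DGE link (B=100): funcPC1 r_s = -0.632, GMV r_s = 0.657 (direct funcPC1 r_s = -0.351)
```

Reading these numbers: the expression summary genePC1 is *negatively*
correlated with the functional abnormality summary and *positively* with
the structural one — the planted (and, in the motivating studies, observed)
opposite-sign structure; the recovered couplings (−0.273, +0.281) sit near
the planted values after estimation-noise attenuation. Bonferroni selection
finds negatively-related genes for funcPC1 and positively-related genes for
GMV, as the coupling signs dictate. The bin-based DGE correlation (−0.632)
is markedly stronger than the direct gene-level one (−0.351): averaging
~100 genes per bin suppresses the noise of the near-zero beta majority.
`res$truth_report` compares everything against the planted ground truth
(here genePC1 recovers the latent gradient at r_s = 0.999 with zero false
positive genes).

With `output_dir` set, every stage's table is written (TSV/GMT/JSON) along
with an MD5 manifest; identical configurations reproduce the files byte for
byte. Real data enter through `pipeline_config(mode = "files", ...)` with
TSV paths, or by calling the stage functions directly.

## Layout

- `R/` — synthetic generators, atlas builder, metrics, effect maps,
  correlates, DGE linkage, enrichment, pipeline orchestration, TSV/GMT/YAML
  I/O.
- `vignettes/imaging-transcriptomics.Rmd` — the methods vignette: model,
  parameter choices with rationale, generator scope and limitations.
- `tests/testthat/` — unit, property and acceptance tests.
- `scripts/acceptance.R` — end-to-end reproduction script (above).
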