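---
title: "Promoter activity, alternative promoters, and methylation: the apmeth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter activity, alternative promoters, and methylation: the apmeth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmeth)
```

## The problem

A gene with several promoters can change *which* promoter it uses
between tumor and normal tissue while its total expression stays flat.
Junction-based promoter activity makes this visible in ordinary bulk
RNA-seq: every spliced read that leaves a promoter's first exon is
evidence that transcription initiated there. `apmeth` quantifies this
signal, calls promoter-level differential events, asks whether promoter
CpG methylation can account for them, and evaluates the clinical value
of the methylation-coupled events. This vignette explains the model, the
parameters that matter, the synthetic data the package validates itself
on, and the choices made where the design was genuinely open.

## Promoter model and activity estimation

Transcripts are grouped into promoters by strand-aware single-linkage
clustering of their first exons: two transcripts share a promoter
exactly when their first exons can be chained through pairwise genomic
overlaps. "Same or nearby TSS" admits several formalisations; we use
first-exon overlap (no fixed bp window) because promoters must map to
distinguishable splice-donor sites for junction counting to be
meaningful — two first exons that overlap cannot be told apart by the
junctions that leave them. Abutting half-open exons do **not** merge.
The promoter TSS is the most 5' member TSS; promoter ids are assigned
after sorting by (chromosome, TSS, gene), so catalogs are reproducible
and input-order independent. Promoters whose first-exon cluster overlaps
an internal exon of a sibling transcript are flagged `is_internal`
(their counts can absorb reads from upstream splicing); the flag is
informational and counts are not adjusted.

Raw activity is the sum of column-7 (unique-mapper) junction reads whose
donor coordinate matches one of the promoter's donor sites exactly.
Exact donor matching, rather than interval overlap, avoids counting one
junction toward two promoters; the clustering above guarantees two
promoters of a gene cannot share a donor. Junctions with STAR strand
code 0 (undefined) are matched against either strand at the
corresponding coordinate.

Normalisation is median-of-ratios on the promoter count matrix
(geometric-mean pseudo-reference over rows with all-positive counts),
the standard choice for count matrices of this shape; with no
all-positive row the package falls back to total-count ratios with a
warning. Absolute activity is `log2(normalized + 1)`. The activity scale
is not dictated by the method itself; we fix log2 because the
downstream minimum-activity threshold (0.25) and fold-change formula are
interpreted on that scale throughout. Relative activity divides by the
gene's summed absolute activity and is `NA` for genes with zero
activity in a sample (their shares are undefined, not zero).

## Differential calling

* **Genes.** Fold change is `log2[(mean norm. tumor + 1)/(mean norm.
  normal + 1)]`; the p-value is a two-sided paired t-test on
  `log2(normalized + 1)` using the design's tumor/normal pairs. The
  contract is one (log2FC, p) pair per gene, so a negative-binomial GLM
  can be swapped in; the paired t on the log scale is the default
  because the acceptance surface is property-based (planted-effect
  recovery), not a replication of any particular count model's
  internals. DEG: p < 0.05 and |log2FC| > 1.
* **Promoters.** Fold change is `log2[(mean abs. tumor + 0.001)/(mean
  abs. normal + 0.001)]` — means of the *log-scale* activities, with a
  0.001 pseudo-activity guarding zero means (a promoter silent in one
  group gets a large, finite fold change ≈ ±10 rather than ±Inf).
  Significance is one-way ANOVA between tumor and normal, computed for
  absolute and relative activity separately; with two groups this is
  exactly the squared pooled t-test, which the suite verifies to 1e-12.
  DRP: p(absolute) < 0.05 and linear |FC| > 1.2.
* **Threshold scale.** "|FC| > 1.2" is interpreted as a linear ratio,
  i.e. |log2FC| > log2(1.2) ≈ 0.263, for both the DRP and AP criteria;
  mixing of log and linear language is common in this literature, so
  the choice is recorded here and in the removal logs.
* **No multiple-testing correction** is applied anywhere by default —
  raw p < 0.05 throughout, matching how such screens are typically
  reported; `p.adjust` can be applied to the returned tables by the
  user, and the calling functions take the thresholds as arguments.

An AP is a DRP on a non-differential gene: gene p ≥ 0.05 **and** linear
gene |FC| < 2 **and** mean absolute activity > 0.25 in both groups
**and** p < 0.05 for both absolute and relative activity **and**
promoter linear |FC| > 1.2. The criteria form one conjunction, so their
order is irrelevant; `identify_aps()` records a per-criterion attrition
table so filter losses are auditable. Promoters of genes with undefined
p-values (all-zero genes, single pairs) are ineligible and logged.

## Methylation linkage

CpGs within ±1 kb of a promoter TSS (inclusive endpoints; distances are
signed and strand-aware, negative = upstream) are correlated with the
promoter's absolute activity across the pooled tumor + normal samples —
pooling follows from the use of a single across-cohort correlation per
promoter; a `samples` argument restricts to one condition when wanted.
The minimum-p CpG is the promoter's representative; ties break toward
smaller |distance|, then probe id, for determinism. Correlation classes:
negative / positive need p < 0.05 and the corresponding sign; mrAPs are
the APs with class negative. Promoters without a usable CpG (none in
the window, or all correlations undefined) are dropped from the
denominator and logged.

Delta beta is `mean(tumor) − mean(normal)` per probe (positive = tumor
hypermethylation). Group-level coupling between methylation change and
activity change is tested only on promoters with |Δβ| > 0.1 (an
alternate 0.2 mode exists); with fewer than three qualifying promoters
the test returns `NA` rather than an unstable estimate.

TSS profiles average betas in 50-bp windows advanced by 25 bp across
±2 kb; a GAM smoother (`mgcv`, thin-plate spline on distance) is the
alternative mode. The windowed mode is the default because it is
deterministic and assumption-free; windows are `[start, start + 50)`
and empty windows are `NA`. Cross-dataset confirmation uses linear-scale
activity (`2^absolute − 1`) pair ratios (confirmed if ≥ 1 validation
pair exceeds 1.2× in the reference direction) and, for methylation, the
same CpG position in validation WGBS with a ±1 kb regional-mean
fallback restricted to CpGs covered in all samples.

## Clinical models

The diagnostic model is L1-penalised logistic regression on mrAP
absolute activities (glmnet; features standardised internally,
coefficients returned on the activity scale). λ is chosen at minimum
mean cross-validated binomial deviance with a fold assignment fixed by a
seed; the 1-SE rule is available via `rule = "1se"` but the minimum rule
is the default — it is the less conservative of the two and keeps the
planted-feature recovery property testable. The printed score omits the
intercept (`Σ activity × coefficient`); ROC AUC is rank-based
(Mann–Whitney, ties at 1/2) and intercept-invariant, so nothing is lost.

Survival dichotomisation re-implements the maximally selected log-rank
cutpoint: candidates are midpoints between consecutive distinct marker
values, candidates leaving a group below `minprop = 0.1` of subjects are
discarded, and the candidate maximising |standardised log-rank
statistic| wins (ties → lower threshold). The reported p-value is the
naive log-rank p at the selected cutpoint, with **no correction for the
selection** — deliberately so, since this mirrors how such cutpoints
are ordinarily reported; the resulting type-I inflation for null markers
is real and users comparing many markers should treat the per-marker
"prognostic" flags as descriptive. Follow-up is administratively
censored at the 10-year horizon (3652.5 days; times must be supplied in
the unit of `horizon`).

## The synthetic study and what it shows

`simulate_hcc_study()` emulates the study conditions the pipeline
targets: 19 tumor/normal pairs; 200 genes with 1–3 promoters (43/37/20%,
about 57% multi-promoter); negative-binomial junction counts (gene
total mean 30 reads, dispersion 0.1, log-normal library factors with
sdlog 0.15); 15% DEG genes (4-fold), 20% AP genes and 5% switch genes.
AP genes shift the target promoter's share by the factor `ap_fc = 2`
while the gene total stays constant — the structural heart of the AP
definition, which makes criterion 1 satisfiable by construction. Target
promoters get small shares (U(0.15, 0.3)) so the share shift clears the
1.2× threshold on the log-activity scale at these modest counts; switch
genes (3 promoters) transfer share from one promoter to another so one
rises ~2× and the other falls hard. Truth flags are evaluated from the
generative means *through the same formulas the caller applies*, so a
planting that lands below a threshold is labelled negative rather than
polluting precision/recall.

Methylation: 5 CpGs per promoter uniform in ±1 kb; for 60% of true-AP
promoters, half the CpGs are coupled as
`beta = plogis(a − 1.5 × activity + N(0, 0.2))` with the intercept
centring betas at 0.5, the rest are independent Beta(2,2). Survival: a
200-subject cohort with one latent high/low methylation group,
bimodal betas (0.35/0.65 ± 0.05) at prognostic CpGs, exponential times
with hazard ratio 3 (baseline 4e-4/day), and 30% censoring implemented
as "censor uniformly before the event with probability 0.3" so the
realised censoring fraction is exact.

What passing tests show — and what they do not: the generator's
promoters always have junction evidence, its library factors are
moderate, its methylation coupling is log-linear, and its survival
signal is one shared dichotomy. Real cohorts bring internal promoters
with inflated counts, batch structure, array detection failures,
non-monotone methylation–activity relationships, and confounded
survival. The suite demonstrates that the statistics recover what they
define under the stated model (AP precision/recall ≥ 0.85 seed-averaged,
mrAP sensitivity ≥ 0.85 for |r| ≥ 0.7 couplings, diagnostic held-out
AUC ≥ 0.95 on separable data, calibrated log-rank p under the null) —
not that those operating characteristics transfer to any real dataset.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF (1-based closed),
  BED (0-based half-open) and 1-based manifest positions are converted
  at the boundaries only.
* Relative activities of an expressed gene sum to 1 within 1e-9.
* ANOVA with any group smaller than 2 finite values, Pearson with fewer
  than 3 complete pairs or a constant vector, paired tests with one
  pair, and delta beta with an all-NA group all return `NA` rather than
  erroring mid-pipeline; callers treat `NA` as ineligible.
* A constant-variance ANOVA input (all values equal) returns p = 1
  (F = 0), not `NA`.
* Betas outside [0, 1] beyond 1e-6 are an input error; within the slack
  they are clamped.
* Ties: representative CpG (p, |distance|, probe id); cutpoint (lower
  threshold); most-significant isoform (p, larger |FC|, transcript id);
  quartile assignment (activity, promoter id).
* Scaling one library by c moves the median-of-ratios pseudo-reference
  by c^(1/m), so size-factor invariance holds exactly on ratios (tested
  in that form), not factor-by-factor.
* Test problem sizes: module tests run a cached 60-gene study; the
  acceptance suite runs ten 200-gene studies for AP recovery, five for
  mrAP sensitivity, 200 seeds for null calibration and 100 for power —
  sizes chosen to estimate each property stably at desk scale.

## Known limitations

* Internal promoter activity is flagged but not corrected; strongly
  internal promoters can show spurious "activity" from upstream
  isoforms.
* The gene-level test is a paired t on log counts, not a count GLM;
  with very low counts or extra-Poisson structure its p-values are
  approximate.
* The maximally selected cutpoint p-value is optimistic (no selection
  correction), and the numeric cutpoint itself is unstable between
  near-equivalent splits — the induced partition is the stable object.
* Pearson correlation is the only association measure for
  methylation–activity links, matching the method being reimplemented;
  rank-based alternatives are not provided.
* Genome builds of annotation, array manifest, and WGBS must agree; no
  liftover is attempted.
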