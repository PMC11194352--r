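---
title: "Longitudinal EWAS, spatial region calling, and region-level QTM: methods and design notes"
author: "ewasdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal EWAS, spatial region calling, and region-level QTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewasdmr)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, the numerical choices, and the design decisions that were
genuinely open.

## 1. Setting and data model

The package targets a longitudinal epigenome-wide study of a two-visit
cohort split into three progression phenotypes (here called *maintainer*,
*progressor*, *reverter*; in the motivating islet-autoimmunity setting
these are children who keep autoantibodies, develop clinical diabetes, or
lose all autoantibodies). Each subject contributes a methylation profile
at a *pre* and a *post* visit. Methylation enters on the M-value scale,
`M = log2(beta / (1 - beta))` (`beta_to_m()`), which is approximately
variance-stabilized and is the modeling scale throughout; beta values are
used only by the probe variability filter.

Probe-level inclusion (`filter_probes()`): autosomal, not within 2 bp of
a known SNP, and a beta range of at least 3% on at least one of the two
array platforms (removal requires invariance on *both*).

## 2. Per-CpG 2-df tests as exact stratum F-tests

The scientific model per probe is a linear mixed model with a subject
random intercept `b_i` and fixed effects for group, visit, group × visit,
age, sex, platform, and six blood-cell proportions (plus two ancestry PCs
in the group-effect model). Two 2-df hypotheses are tested: the
group × visit interaction (does the pre→post *change* differ by group?)
and the group main effect on the visit average.

**Why not a likelihood-ratio chi-square.** With 143 subjects and ~13
fixed-effect parameters, the ML likelihood-ratio test of the 2-df
hypotheses is measurably anticonservative: on a 2,000-probe null
simulation its empirical size at nominal 0.05 was ~0.07, outside the
exact binomial 99% interval the package's own calibration test demands.

**The balanced decomposition.** Because every subject has exactly one pre
and one post visit, the random-intercept model decomposes exactly into
two independent strata:

* *within-subject*: paired differences `d_i = M_post - M_pre`, in which
  `b_i` and every visit-constant covariate (sex, platform, ancestry)
  cancel, leaving `d_i ~ group + Δage + Δcells` with iid errors of
  variance `2σ²`. The interaction hypothesis is exactly the 2-df group
  term here, and the F-test is exact under normality.
* *between-subject*: visit means `m_i = (M_post + M_pre)/2`, leaving
  `m_i ~ group + mean age + sex + platform + mean cells + PC1 + PC2` with
  iid errors of variance `σ_b² + σ²/2`. The group main effect is exactly
  the 2-df group term here. The visit main effect is inestimable in this
  stratum, which is immaterial to the group hypothesis.

`dmp_fit()` fits both strata by QR least squares with one factorization
per design (the design is shared across probes, so per-probe work is two
residual projections), making a 2,000-probe scan a matter of seconds.
Reported effects are the model-implied per-group visit slopes
(within stratum, at zero covariate change) and the pairwise contrasts
P−R, R−M, P−M (between stratum). The six cell proportions sum to one and
are collinear with the intercept; one proportion column (granulocytes,
the largest and most redundant) is dropped automatically. Probes with
zero variance or non-finite values are flagged and excluded from the
BH-FDR adjustment (`bh_fdr()`, significance at FDR < 0.10); there is no
imputation, and the group model is complete-case in the ancestry PCs.

## 3. Spatial region calling

The regional machinery is a from-scratch implementation of the comb-p
idea, parameterized by the published defaults: seed p-value 0.1,
window 500 bp, bin/step 50 bp, and Sidak alpha 0.10.

1. **ACF estimation** (`estimate_acf()`): probe p-values are transformed
   one-sided, `z = Φ⁻¹(1 − p)`, and for each distance bin (0,50], …,
   (450,500] the Pearson correlation is computed over all
   same-chromosome probe pairs in the bin. Bins with fewer than 10 pairs
   inherit the previous bin's value (the first bin falls back to 0 with a
   warning). Estimates are clipped to [0, 1] before use: negative
   estimates would deflate the combination variance, and sampling noise
   around zero is the more defensible interpretation.
2. **Neighbourhood correction** (`slk_correct()`): each probe is combined
   with all probes within ±500 bp via Stouffer–Liptak,
   `z_comb = Σz_i / sqrt(k + 2 Σ_{i<j} σ(d_ij))`. Pair distances inside
   a neighbourhood can reach twice the window while the ACF is estimated
   only to the window; distances beyond the last bin take the terminal
   bin's correlation (slightly conservative).
3. **Candidate runs** (`find_candidate_regions()`): maximal runs of
   *consecutive* probes with corrected p below the seed threshold, broken
   by a probe at/above the threshold or a gap over 500 bp. (A
   non-significant probe breaks the run even if later probes recover —
   the behaviour of the original sliding-window peak finders.)
4. **Region p** (`region_pvalue()`): one Stouffer–Liptak combination of
   the region's *raw* member p-values (the corrected values are already
   neighbourhood-smoothed; combining them again would double-count
   evidence). Singletons keep their raw p.
5. **Sidak** (`sidak_adjust()`): `1 − (1 − p)^(coverage/width)`, where
   coverage is the summed per-chromosome span of analyzed probes — the
   number of similarly sized regions the covered genome could hold. The
   `log1p/expm1` form preserves precision for small p.

Retention (`filter_delta_dmrs()` / `filter_mu_dmrs()`): at least 4
probes, Sidak p < 0.10, and 100% direction consistency — all member
probes' within-group slopes share one sign in at least one group (Δ
track), or all member probes' estimated contrasts share one sign for at
least one pairwise comparison (μ track). A slope of exactly zero counts
with the majority sign (configurable via `zero_with_majority`); with a
50/50 sign split the consistency share is 0.5 by construction.

## 4. Region scores and QTM testing

For each retained region, covariates are regressed out of each member
CpG with a subject-random-intercept model
(`residualize_repeated()`); the random intercept is *not* subtracted, so
within-subject change survives residualization. Residuals are collapsed
per subject (`paired_contrast()`): post − pre for Δ regions, the visit
mean for μ regions (which additionally residualize the ancestry PCs).
The region score is the first principal component across the region's
standardized CpG columns (`region_pc1()`); PC1's sign is indeterminate,
so orientation is fixed by positive correlation with the across-CpG row
mean — an increasing score always means increasing methylation (or
increasing change), making statements like "methylation positively
associated with expression" well defined. Flipping the orientation flips
every downstream statistic's sign and no p-value.

*eQTM*: post-visit expression is residualized on age and sex; genes are
eligible when their TSS lies within ±500 kb of the region midpoint
(`floor((start + stop)/2)`); minus-strand genes take the gene end as TSS
(`tss_from_genes()` — the annotation rule is configurable by supplying a
custom TSS table). Association is Spearman's rho on midranks with the
t-approximation p-value (the t approximation is used uniformly rather
than cor.test's n- and tie-dependent switching between exact and AS89
backends), and BH-FDR is applied over all cis pairs of the candidate
family.

*metQTM*: metabolites are Box-Cox transformed
(`boxcox_transform()`, ML lambda on the grid −2…2 by 0.1, natural log at
λ = 0, a `1 − min` shift for nonpositive values), residualized on age and
sex within each visit, collapsed to per-subject deltas (Δ candidates) or
means (μ candidates), and regressed on the region score with both sides
z-scored, so the slope *is* the standardized beta (numerically the
Pearson r). BH-FDR is applied separately per metabolite panel
(HILIC/Lipid/GCTOF), mirroring platform-stratified multiplicity control.

## 5. The synthetic cohort: what it emulates, and what a green test means

`cohort_design()` defaults *are* the emulated study: group sizes
60/42/41 (maintainer/progressor/reverter), two visits per subject,
lognormal ages with per-group medians 5.7/2.2/6.0 years pre and
8.0/4.9/7.1 post (ordering progressor < reverter ≈ maintainer; the scale
`sdlog = 1` reflects the wide printed IQRs), balanced sex, random
platform assignment independent of phenotype (both visits on one
platform), Dirichlet cell proportions with concentration proportional to
typical pediatric whole-blood medians (total concentration 40), two
standard-normal ancestry PCs with 2 subjects nulled out to exercise the
complete-case rule, and expression/metabolite overlap subsets of 36 and
110 subjects.

The methylation signal model (`generate_methylation()`) is additive on
the M scale: a bimodal probe baseline, probe-specific covariate effects,
a subject intercept (SD 0.30 M-units), planted per-group mean offsets
(μ regions) and visit slopes (Δ regions), within-cluster noise with
correlation `exp(−0.01 · distance)` (≈0.6 at 50 bp, ≈0.007 at 500 bp) and
SD 0.10, plus independent residual SD 0.15. The noise scales were chosen
once as a realistic replicate-level M-value noise for blood arrays and
are deliberately conservative; the recovery study in the acceptance suite
shows that at these scales a planted 8-probe region with slope gaps of
0.12–0.14 M-units sits near the edge of detectability at desk-scale
genomic coverage (~84% of replicates yield a retained overlapping region,
against a 90% criterion) — an honest power statement about this world,
not a calibration target. Linked omics features (`generate_linked_omics()`)
are tuned to population targets via the bivariate-normal identity
`rho_pearson = 2 sin(π rho_s / 6)` for Spearman links and unit-variance
construction for standardized-beta links.

What the generator does **not** emulate: IDAT-level intensities and
normalization, probe-chemistry (type I/II) artifacts, batch/plate layout,
cell-proportion deconvolution error, non-Gaussian methylation
distributions, and trans effects. A green test therefore establishes
correctness and calibration of the statistical machinery under the
declared signal model — not robustness to array artifacts upstream of it.

## 6. Numerical choices and conventions

* p-values are clamped to `[1e−16, 1 − 1e−16]` before z-transformation;
  betas outside (0,1) are clamped to `[1e−6, 1 − 1e−6]` with a warning.
* Leading-probe ties break by lowest genomic position.
* Manifest and internal region coordinates are 1-based points/inclusive;
  BED output is 0-based half-open; `coords_to_bed()`/`bed_to_coords()`
  are the only conversion sites and round-trip exactly.
* Matrix TSVs are written with 17 significant digits so doubles survive
  the text round trip bit-identically; missing values are empty fields,
  never sentinels.
* Configuration is JSON (`read_config()`); no YAML parser is available in
  the supported environment, and JSON was the documented fallback. All
  thresholds default to the published values (seed p 0.1, window 500,
  step 50, min probes 4, Sidak 0.10, FDR 0.10, cis ±500 kb).
* Output files carry a `# ewasdmr config=<hash> seed=<n>` stamp; the hash
  covers analysis parameters only, so re-running into a different
  directory reproduces byte-identical numeric content.
* Every generator accepts a seed and restores the caller's RNG state;
  identical seeds give bit-identical outputs.

## 7. Open design decisions, as resolved

* **Exact stratum F-tests instead of ML likelihood-ratio chi-squares**
  for the 2-df hypotheses — adopted after the LRT failed the package's
  own null-calibration invariant (Section 2). A corollary: no variance
  component is iterated, so there is no boundary/singular-fit pathway to
  fall back from.
* **Platform assignment independent of phenotype** in the generator (the
  emulated study randomized platforms; a confounded option is available
  by editing the sample sheet, not a generator default).
* **ACF step = the 50 bp bin width; 500 bp is both the combination window
  and the run-gap limit** — the step parameter has no other referent in
  the procedure.
* **Coverage for Sidak is the spanned extent of analyzed probes** per
  chromosome, not probe count × step; alternatives can be passed to
  `sidak_adjust()` directly.
* **Region p from raw member p-values**, candidates from corrected ones
  (Section 3).
* **Batch/plate terms are not modeled by default**; the covariate set of
  `score_regions()`/`dmp_fit()` is fixed by the study design, and a batch
  column can be added to the sample sheet and passed through
  `residualize_repeated()`'s covariate list where needed.
* **Metabolite contrast pairing**: delta scores against metabolite deltas
  for Δ candidates, mean scores against metabolite means for μ
  candidates; cross-combinations are not computed by default.

## 8. Limitations

Exactness of the stratum F-tests depends on the balanced two-visit
design; unbalanced data (missing visits) are dropped subject-wise rather
than modeled. The Stouffer–Liptak variance term treats the clipped,
binned ACF as known; very sparse chromosomes fall back to neighbouring
bins and, in the extreme, to zero correlation. Spearman p-values use the
t approximation, adequate at the n ≥ 5 enforced minimum but approximate
for n < 10 with heavy ties. The Sidak correction assumes the covered
genome could be tiled by similarly sized regions, which is conservative
for clustered probe layouts. The eQTM stage uses post-visit expression
only — with a single expression time point, direction of causation and
expression *change* are out of reach.
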