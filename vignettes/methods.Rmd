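---
title: "Methods: dysbiosis scoring and immune-microbe association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dysbiosis scoring and immune-microbe association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dysbionet implements the downstream analysis chain of a longitudinal
HIV-microbiome study design: three cohorts (ART-naïve people living with
HIV starting therapy, ART-experienced, healthy controls), two locations
(rural, urban), two visits 24 weeks apart, an ASV count table with a
rooted phylogeny, and an eight-marker immune panel (CD38+HLA-DR+
activation, PD-1 exhaustion and CD103 trafficking percentages on CD4+
and CD8+ T cells; plasma IL-6 in pg/mL and CRP in mg/L). This vignette
records the models, the parameters that matter, and the design decisions
taken where the workflow was genuinely open.

## Cohort preparation

Viral-load rules use strict inequalities as printed in clinical
reporting: an ART-naïve baseline sample is *inconsistent* when viral
load < 20 copies/mL (suppression contradicts declared untreated status);
ART-naïve week-24 and ART-experienced baseline samples are *viremic*
when viral load > 200 copies/mL. The baseline filter removes
inconsistent naïve and baseline-viremic experienced participants; the
longitudinal filter then removes participants with a single visit and
naïve participants without week-24 virologic control, leaving a strict
two-samples-per-participant set. Every `filter_report` conserves counts
(retained + excluded = input) and the filters are idempotent.

Missing CD4-lineage markers (the CD4 activation, PD-1 and CD103
percentages) are imputed with the mean of the non-missing values of the
same marker. The stratum of that mean is a design choice: the source
workflow says only "the average". We default to the **cohort × week**
mean, because a global mean would leak information across cohorts whose
marker distributions differ by design; `strata = "global"` is available
for sensitivity analysis.

Rarefaction subsamples each retained sample without replacement to a
fixed depth (the reference workflow's choice, 16,645 reads, is the
scripts' default), one RNG draw per sample in sample-ID sort order so
results are reproducible and insertion-order independent. Shallower
samples are dropped and logged, never partially kept. The prevalence
filter retains features seen in **strictly more than** 20% of samples, so
a feature at exactly the threshold is dropped.

## Diversity core

Shannon entropy is computed in bits (log base 2, the convention of the
standard amplicon core-metrics pipelines); the base is an argument and is
recorded on the result.

Weighted UniFrac between samples A and B is
`Σ_l b_l |p_A(l) − p_B(l)|` over tree branches, where `p_X(l)` is the
fraction of sample X's reads on leaves below branch `l`. The default is
the **raw (unnormalized)** variant — the core-metrics default; whether
the normalized variant was used upstream is not documented, so the
normalized form (dividing by `Σ_l b_l (p_A(l)+p_B(l))`) sits behind a
flag. The implementation accumulates branch mass by postorder traversal
and is tested against a brute-force oracle that enumerates every
branch's descendant leaf set, and against an independent implementation.

PCoA double-centers `−D²/2` (Gower) and eigendecomposes. Numerical
choices: negative eigenvalues (non-Euclidean input) are **dropped with no
correction** and excluded from the proportion-explained denominator —
the common default; Lingoes/Cailliez corrections are out of scope. Each
axis is oriented so the lexicographically smallest sample ID has a
non-negative coordinate (ties broken by the next sample), which removes
reflection nondeterminism from downstream regressions and tests. Biplot
feature coordinates are abundance-weighted means of sample coordinates;
importance is the Euclidean norm over retained axes, so a feature spread
evenly over samples sits at the origin of the centered scores.

PERMANOVA uses sequential (Type-I) sums of squares in the order terms
are listed and the permutation p-value `(1 + #{F* ≥ F_obs})/(1 + n_perm)`,
delegating to `vegan::adonis2(by = "terms")` — the canonical
implementation this workflow cites. With `strata`, permutations shuffle
samples only within blocks; with participant blocks this respects
repeated measures, but note that a covariate constant within participant
(e.g. location) cannot be displaced by within-participant permutations,
so its p-value under participant strata is close to uninformative — the
test is about within-participant terms such as week.

## Dysbiosis and delta regressions

A sample's dysbiosis is its mean weighted-UniFrac distance to all
healthy-control samples **of the same week**; week-0 samples are never
referenced against week-24 controls. Scores are defined for the two PLWH
cohorts; an explicitly flagged extension (`include_hc = TRUE`) scores
control samples against the other controls of their week (self excluded),
for control-side correlates. Scores are invariant to sample order, and a
constant added to all distances shifts every score by exactly that
constant.

Delta regressions fit, per stratum (cohort, or cohort × location),
ordinary least squares of `Δ = week24 − week0` on the baseline value,
independently — no pooling, no interaction model, matching the
stratified presentation of the source workflow. Interpretation caveat
(regression to the mean): if week-24 values were independent of
baseline, the slope would concentrate at −1; persistence plus
independent noise gives a slope near 0. Both signatures are verified by
simulation in the test suite. With zero variance in the deltas the slope
and intercept are 0 and R² is reported as 0. Exposure correlates
(months of cotrimoxazole vs dysbiosis or Shannon) are emitted as both
Pearson and Spearman coefficients, since the convention is not fixed.

## Immune statistics

Inter-cohort comparisons use Kruskal–Wallis (tie-corrected H) with
Dunn's post hoc on mean ranks and tie-corrected variance. The post-hoc
adjustment is not fixed by convention here, so the default is
Benjamini–Hochberg within each marker's pairwise family with an
unadjusted option. The within-participant week-0 vs week-24 comparison
is a Wilcoxon signed-rank test — the standard paired rank test, despite
the looser "paired Mann–Whitney U" phrasing often used — with zero
differences dropped, the exact distribution for ≤ 25 untied differences,
and the tie-corrected normal approximation otherwise. Note the
signed-rank statistic ranks |differences|, so it is invariant to
positive affine maps of the values, not to arbitrary monotone maps.

The longitudinal fixed-effects model is
`marker ~ cohort + week + cohort:week` (reference: healthy controls,
week 0) by OLS with cluster-robust sandwich covariance grouped by
participant, small-sample factor `G/(G−1) · (n−1)/(n−k)` and t tests on
`G − 1` degrees of freedom — the fixed-effects-tooling default family.
A mixed-effects random-intercept variant for PCoA-axis models is **not**
implemented; the PC axes plus this cluster-robust OLS are the supported
approximation, stated rather than silently substituted.

Backward-stepwise selection starts from forced-in covariates (location
always; viral load for PLWH; diagnosis date for the ART-experienced)
plus the candidate pool, and removes the candidate whose removal most
improves AIC (default) or the least significant candidate at p ≥ 0.05
(variant), never touching forced-in terms, recording every step, and
flagging final models whose overall F-test p ≥ 0.05 as "model NS". AIC
was chosen as the default because the criterion is unspecified upstream
and AIC backward elimination is the reproducible textbook default; the
trace makes either auditably re-runnable.

## Association network

Module binning is SCNIC-style but pinned, because "default parameters"
are version-dependent: Spearman correlation on relative abundances,
complete-linkage clustering on `1 − r`, cut at height `1 − min_r` with
`min_r = 0.35`, which guarantees every within-module pair correlates at
least `min_r`. Module abundance is the element-wise sum of member
counts; constant features cannot be correlated and stay unbinned with a
warning. Settings are recorded in the output.

Each (marker, feature) pair is fit by OLS:
`marker ~ read count + feature + cohort + feature:cohort`, on
**non-rarefied** relative abundances after the prevalence filter, with
the per-sample total read count as a nuisance covariate absorbing depth
differences. The `*` expansion includes the cohort main effect. The
reference cohort is ART-naïve (three-cohort mode) or ART-experienced
(two-cohort mode); non-reference slopes are reference + interaction, and
slope-difference tests are Wald tests on the interaction coefficients of
the same fit — no refitting. The overall F compares the full model to
the read-count-only null, since read count is nuisance, not signal.

The five-criterion cascade, applied to the family of **all marker ×
feature fits of one timepoint** (the per-timepoint family mirrors the
per-timepoint networks; a per-marker family variant is a documented
alternative): Benjamini–Hochberg FDR on the overall-F p < 0.2; adjusted
R² > 0.25; reference slope p < 0.05; at least one interaction p < 0.05;
max |DFFITS| < 2. DFFITS is
`t_i √(h_i/(1−h_i))` with externally studentized residuals; a
numerically zero-residual fit returns all zeros (the limit convention,
so perfect toy fits pass rather than crash), and exact leverage points
(`h_i = 1`) are reported infinite and flagged. Edges carry the sign of
the reference-cohort slope and a display width of `−log10(p_slope)`;
networks export as JSON plus an edge TSV and round-trip losslessly.

## The synthetic cohort generator

`generate_dataset()` is first-class, tested code that emulates the
statistical structure the analyses assume — not the raw data:

- **Counts**: Dirichlet-multinomial per sample (concentration 50 by
  default — the simplest model with realistic overdispersion), mean
  composition a smooth decreasing abundance profile. Two designated
  blocks of 10% of features each carry the rural↔urban gradient
  (`gradient_strength`, a log-scale multiplier, default 1.5), mirroring
  the Prevotella-rich vs Bacteroides-rich axis that dominates PC1 in
  such cohorts; block membership is recorded in the ground-truth sidecar
  for test assertions. Sequencing depth is negative-binomial
  (mean 25,000, size 10), floored at 100 reads; row sums equal the drawn
  depths exactly.
- **Viral loads**: log-normal with point masses at zero for suppressed
  participants; per-cohort event probabilities (`viremia_rates`) default
  to the enrollment-flow fractions of the worked example
  (14/81 naïve baseline-inconsistent, 15/67 naïve week-24 failure,
  6/39 experienced baseline viremia), and `dropout_rate` defaults to
  14/142, so expected exclusion fractions match the cascade the package
  is tested against.
- **Immune panel**: marker = baseline + cohort effect + week effect
  (naïve improving on therapy) + participant random intercept
  (`pid_intercept_sd`, default 2) + noise (`immune_noise_sd`, default 3,
  marker units) + planted effects. Percentages clip to [0, 100],
  concentrations to ≥ 0. **Planted effects are mean-centered within the
  planted cohort**: a planted slope changes the marker–microbe
  covariance without shifting the cohort's marker mean. This keeps
  planted slopes and cohort-mean effects orthogonal and independently
  configurable; an uncentered slope would re-create the cohort shift
  implicitly, letting every feature's model pass the adjusted-R² gate
  through the cohort main effect and inflating reference-slope
  t-statistics via pooled-residual heteroskedasticity, which makes
  false-edge behavior a property of the parametrization rather than of
  the cascade under test. `immune_cohort_effects = FALSE` switches the
  built-in cohort/week shifts off, giving the no-nuisance configuration
  used for planted-edge recovery checks.
- **Planted effect sizes**: no effect sizes are documented for real
  microbe–immune associations, so defaults in tests (|slope| = 250 on a
  ~4–5% mean-abundance feature, i.e. a signal SD of roughly twice the
  residual SD) were sized once, analytically, so that a planted edge
  clears the adjusted-R² > 0.25 criterion at the default noise — chosen
  for testability, not claimed realism.
- **Determinism**: one configured seed; stage sub-streams derive from it
  by fixed offsets (metadata, counts, immune, missingness, tree), so
  changing the feature count cannot reshuffle the metadata draws, and
  regenerating with the same configuration is byte-identical.
- **Missingness** is completely at random, CD4-lineage markers only.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: taxonomic identity and phylogenetic signal
in composition (the tree is random, so UniFrac structure beyond the
planted gradient is noise); diet, antibiotic and socio-economic
covariates; compositional zero-inflation beyond what the
Dirichlet-multinomial produces; selection effects in loss to follow-up
(dropout is random); and any nonlinear or non-Gaussian microbe–immune
coupling.

## Problem sizes and calibration checks

The test and acceptance workloads were sized as desk-scale analyses: the
UniFrac oracle comparison uses 100 random instances of up to 10 leaves
and 6 samples (agreement to 1e-10); PCoA is checked on hand-computable
3-point matrices and random planar configurations (reconstruction to
1e-8); PERMANOVA is compared to full enumeration at n = 6 and calibrated
against a 500-simulation null at α = 0.05 (within 3 Monte-Carlo SEs),
with and without participant strata; DFFITS is compared to
leave-one-out refits on 50 random regressions (1e-8); planted-edge
recovery runs the full pipeline at 40 participants per cohort × location
cell with 5 planted naïve-only edges and a 200-seed global-null sweep at
a smaller size (10 per cell, 40 features). The enrollment worked example
reconstructs a printed exclusion flow (162 enrolled → 142 baseline →
113 longitudinal participants / 226 samples; 22.4% naïve virologic
failure, 15.4% experienced baseline viremia) from its stated counts.

## Known limitations

- Raw-read processing (denoising, taxonomy, tree insertion) is out of
  scope; the package starts from a count table and a rooted tree.
- Differential-abundance modeling (e.g. bias-corrected compositional
  regression) is out of scope.
- The mixed-effects ordination model is approximated by cluster-robust
  OLS, as stated above.
- Location effects cannot be tested by participant-stratified
  PERMANOVA (constant within blocks); report them from unstratified or
  baseline-only analyses.
- The BIOM reader requires the optional `biomformat` package; the native
  interchange formats are TSV and newick.
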