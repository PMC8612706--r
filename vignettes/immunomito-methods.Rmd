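---
title: "Methods: models, parameters and design choices in immunomito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in immunomito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunomito)
```

`immunomito` analyses mitochondrial phenotypes — citrate synthase (CS) and
respiratory-chain (RC) complex I, II and IV activities, plus mtDNA copy
number (mtDNAcn) — measured in purified immune cell subtypes and in mixed
PBMCs. This vignette is the package's own account of the science: the models
it assumes, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the design decisions taken where the problem was genuinely open.

## 1. From raw measurements to features

**Replicate aggregation.** Enzymatic activities arrive as triplicate wells
per sample × enzyme. `aggregate_replicates()` reports the mean and a
technical CV = sd/mean. The CV uses the *sample* (n−1) standard deviation;
this convention is applied package-wide (weekly CVs, SEMs, scaled series)
and is configurable (`sd_type = "population"`). Samples whose replicate CV
exceeds a QC threshold (default 15%) are flagged, not removed — assay-level
technical CVs of a few percent are typical for these enzymes, and the
threshold is deliberately lenient.

**Run-order drift.** Large assay campaigns (hundreds of samples over many
plates) drift. `batch_order_adjust()` fits a linear trend of activity
against run position on designated reference replicates and subtracts it,
anchored at the first reference, so the first and last reference replicates
agree. Only "linear adjustment" is specified by the source protocols, so two
open choices had to be made: the drift is modelled as *additive* by default
(a multiplicative mode is provided), and it is fitted across the *whole run*
by default (`per_plate = TRUE` switches to per-plate fits). Adjusted values
below zero are clipped at zero and flagged. The transform is idempotent: the
test suite asserts that adjusting an adjusted table is the identity.

**mtDNA copy number.** Two duplex TaqMan assays measure a mitochondrial and
a nuclear amplicon in the same well (ND1/B2M, COX1/RNaseP). Replicate Cts
are averaged per assay, ΔCt = Ct~nuc~ − Ct~mt~, and

$$\mathrm{mtDNAcn} = 2 \times 2^{\Delta Ct},$$

averaged across the two assays. The leading factor 2 reflects the *diploid*
nuclear reference locus: at ΔCt = 0 the mitochondrial amplicon is as
abundant as a locus present in two copies per cell. One missing assay
degrades to the other with a warning; values above 10⁵ copies/cell are
flagged as probable platelet or cell-free contamination.

## 2. The MHI composite

The mitochondrial health index summarizes RC capacity per unit of
mitochondrial content: RC features up, content features down. The exact
functional form in the source literature is not reproducible from its text
("mean-centered features" combined as (CI+CII+CIV)/(CS+mtDNAcn)): literal
mean-*subtraction* makes the denominator cross zero for below-average
samples, which cannot have been intended. The package therefore normalizes
each feature by its reference mean in *ratio* form (x′ = x/mean), and
balances the numerator and denominator by their feature counts:

$$\mathrm{MHI} = \frac{(CI' + CII' + CIV')/3}{(CS' + \mathrm{mtDNAcn}')/2}
\times 100 .$$

A sample at the reference means scores exactly 100; MHI is invariant to
rescaling all five features jointly, strictly increasing in each RC feature
and decreasing in each content feature. The reference stratum is *per cell
subtype* by default (each subtype is compared to its own cohort
distribution); a global-reference mode exists. Because the scaling is a
package choice, cross-study MHI values should be compared only qualitatively.

## 3. The mitotype registry

Mitotypes are ratio indices over the five features, designed to compare
cell types on scale-free axes. The default registry holds 16 mathematically
distinct indices in five categories:

```{r}
reg <- default_registry()
table(reg$category)[unique(reg$category)]
```

The exact list in the source supplementary material was not available to
this implementation; the registry is a reconstruction constrained by the
five printed category names and the printed example indices (mtDNAcn/CS,
CII/mtDNAcn, CI/mtDNAcn vs mtDNAcn/CS, CI/CS). It is deliberately
config-overridable (`read_registry("registry.json")`) so the exact published
list can be dropped in without code changes.

One mathematical subtlety is asserted rather than assumed: most indices have
homogeneity degree 0 (unchanged when all five features are multiplied by a
constant), but the three 'enzyme per mtDNA density' indices, e.g.
CI/(mtDNAcn/CS), have degree +1, because their denominator is itself
scale-free. `scale_degree()` computes the degree numerically and the test
suite pins the expected values.

**Effect ranking and enrichment.** For sex, Hedges' g is computed per
(mitotype × subtype) with the convention g > 0 = higher in women; for age,
Spearman r. The ranked grid is 16 × 9 = 144 combinations when PBMCs are
included alongside the 8 purified subtypes. Category enrichment counts
positive vs negative effects per category and tests the split against 50:50
with a one-sample chi-square goodness-of-fit test (df = 1); the source's
test construction is not printed, so the goodness-of-fit form was chosen
over a contingency-table form, and zero-effect combinations are excluded
from the counts (flagged p = 1 when a whole category is zero).

## 4. Cross-sectional statistics

* **Hedges' g** with J = 1 − 3/(4·df − 1), df-weighted pooled sd,
  SE² = (n₁+n₂)/(n₁n₂) + g²/(2·df), 95% CI = g ± 1.96·SE, and a
  Mann-Whitney p-value (exact enumeration for n₁+n₂ ≤ 20 without ties,
  normal approximation with tie and continuity correction otherwise).
* **Spearman r** on mid-ranks with the t-approximation p-value; the
  **partial** variant rank-transforms x and y, residualizes both on the
  covariates (sex, age) by least squares and correlates the residuals,
  dropping collinear covariates with a warning.
* **Fisher-z averaging**: r_z′ = tanh(mean(atanh(r))); correlations at ±1
  are clipped to ±0.999999 first. For the biomarker strength comparison the
  average runs over |r|; for co-regulation matrices signed averaging is the
  default with an `absolute = TRUE` switch (the source is explicit about
  absolute values only for the biomarker comparison).
* **Kruskal-Wallis** H with tie correction and **Dunn** z statistics
  against a designated reference group only (the purified-subtypes-vs-PBMC
  design), Bonferroni-adjusted over those comparisons; **Friedman** with tie
  correction and Dunn comparisons against the reference condition for the
  matched depletion fractions. Both match `stats::kruskal.test()` /
  `stats::friedman.test()` to 1e-10 in the test suite, which serve as
  oracles, not as the implementation.
* No global multiple-testing correction is applied across the feature ×
  subtype grid, matching the exploratory design of the source analyses; an
  FDR switch is deliberately *not* bundled into the ranking functions so
  that reported p-values mean what they say.

**Co-regulation** asks whether a feature is a coherent person-level
property: pivot to participant × subtype, Spearman per subtype pair over
participants present in both (pairwise-complete, minimum 4 shared
participants), Fisher-average the off-diagonal. Pairwise completeness
matters because only the six most abundant subtypes are collected per
person, so the matrix is inherently incomplete.

## 5. Repeated-measures dynamics

Weekly series are summarized by the CV (sd/mean across all time points) and
the rMSSD, `sqrt(mean((x[t+1] − x[t])²))`, computed over *consecutive
observed weeks only* — a missing week breaks the successive pair rather
than bridging the gap, because "successive differences" means adjacent
weeks. Scaled trajectories use (x − mean)/sd so one unit is one SD.
`mitotype_conservation()` contrasts the dominant between-subtype |g| per
mitotype with the cohort-vs-repeat |g| within subtypes; the source's
aggregation of its "12.5-fold larger" figure is not spelled out, so the
ratio of means is the default with a median mode provided.

## 6. The synthetic world

The generator emulates the structure of the study the analysis chain is
built for: ~21 participants (11 women, 10 men) aged 20–60, up to 8 sorted
subtypes + PBMCs each, 9 weekly repeats for one participant, and
platelet-depletion triplets. Its defaults *are* the stated world:

* **mtDNAcn means**: B cells 451, CD8⁺ naïve 427, neutrophils 128, NK 205,
  other T subtypes 300 copies/cell. Enzyme activity means are free
  parameters chosen to reproduce the printed qualitative ordering (CS and
  RC highest in monocytes/B cells; lowest RC in neutrophils, lowest CS in
  CD4⁺ naïve) with a maximal cell-type fold below the mtDNAcn fold range.
* **Sex effects**: ×1.29 on CS in CD8⁺ CM-EM cells and ×1.26 on CI in
  monocytes for women; **age slopes**: +10%/decade mtDNAcn in CD4⁺ naïve
  cells and monocytes, −7%/decade CS in neutrophils, all linear in decades
  from age 20.
* **Platelets**: baseline 260×10⁹/L at age 20, compounded 6% decline per
  decade, ×1.2 female/male ratio, log-normal CV 0.15. The contamination term
  adds `coefficient × platelet count` to each PBMC activity and to the
  mtDNAcn *numerator only* (platelets carry mtDNA but no nuclear genome —
  this reproduces the direction of platelet inflation of PBMC mtDNAcn).
  Coefficients are parameterized as the *share* of the PBMC signal at the
  reference count of 250: CS 0.20, CI 0.15, CII 0.12, CIV 0, mtDNAcn 0.15 —
  inside the 9–22%-except-CIV band established by depletion experiments.
* **Mixture**: PBMC = composition-weighted average of the *mononuclear*
  subtype vectors (neutrophils are excluded and the weights renormalized,
  since Ficoll-isolated PBMCs contain no granulocytes) + the platelet term.
  At zero noise this identity is exact and is asserted per sample.
* **Dispersion**: no between-person SDs are printed for any cell-type
  feature, so dispersion is a free parameter. The default log-normal CV of
  0.25 sits inside the printed 4.1–64.4% weekly-variation band; log-normal
  noise is mean-unbiased (`exp(N(−σ²/2, σ²))`) so configured means are hit
  exactly in expectation. Chosen once; not revisited.
* **Weekly dynamics**: multiplicative stationary AR(1) in log space with
  lag-1 autocorrelation 0.3 and weekly CV 0.2 per feature. The source gives
  no temporal model, only CV/rMSSD ranges; AR(1) is the minimal model with
  a tunable successive-difference structure. σ is chosen as
  `sqrt(log(1+cv²))` so the marginal CV equals the configured value exactly.
* **Depletion triplets**: total = leukocyte + platelet term; depleted =
  leukocyte + (1−efficiency)·platelet; eluate = platelet + carryover·
  leukocyte (defaults: efficiency 1, carryover 0.1, measurement CV 0.05).

Everything generated carries a `truth` channel (latent weights, platelet
terms, generating config), so recovery tests compare estimates against the
*realized* truth, not against constants.

**What a green test does and does not establish.** The generator reproduces
the first- and second-moment structure the estimators assume: log-normal
positive features, multiplicative covariate effects, Dirichlet composition,
a linear-in-count platelet term. It does not emulate FACS gating artifacts,
antibody spectra, cytometer noise, assay-plate spatial effects beyond a
linear drift, cell-type misclassification, or the two external platelet
epidemiology cohorts. A passing recovery test therefore validates estimator
correctness under the stated model, not robustness to real-data pathology.
Recovery acceptance runs use a reduced between-person CV of 0.10 — the
"small noise" setting under which ±2–3-point recovery tolerances are
meaningful tests of correctness rather than lottery tickets; the default CV
0.25 remains the realistic-world setting used everywhere else.

## 7. Numerical choices and degenerate inputs

* Zero pooled sd: g = 0 for identical groups, ±Inf flagged otherwise.
* Constant series: scaled to all zeros with a `constant` flag; constant
  inputs to Spearman return NA with a warning.
* Correlations of exactly ±1 are clipped to ±0.999999 before Fisher
  averaging (atanh(±1) is infinite).
* Ranking ties are broken deterministically by (category, name, subtype).
* Negative drift-adjusted activities and negative raw platelet shares clip
  to 0 with flags; the CIV share is expected to clip under noise because its
  configured share is 0.
* All generator randomness flows through one integer seed; generators save
  and restore the caller's RNG state, and fixed seed ⇒ bit-identical output
  (asserted). Derived seeds stay within 32-bit integer range.

## 8. Known limitations

* The MHI scaling and the exact 16-index composition are reconstructions
  (Sections 2–3); both are config-overridable but absolute agreement with
  the source values cannot be claimed.
* Depletion efficiency is assumed (default 1.0), so platelet shares are
  lower bounds when true efficiency is below 1.
* The repeat-participant design is a single person; `mitotype_conservation()`
  treats it as such and makes no population claim.
* No mixed-effects or longitudinal model is fitted — the dynamics module is
  descriptive by design (CV, rMSSD, correlation), matching the source
  analyses.
* Printed cohort-level results that depend on the study's raw per-sample
  data (e.g. specific co-regulation averages r_z′ = 0.63/0.53/0.37) are not
  asserted numerically anywhere: the tests only assert quantities the
  package itself computes from stated inputs.
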