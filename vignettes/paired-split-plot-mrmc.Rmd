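---
title: "Paired split-plot MRMC noninferiority analysis: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired split-plot MRMC noninferiority analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedmrmc)
```

## The scientific problem

Multireader multicase (MRMC) observer studies ask whether a new imaging
protocol can replace an established one. Here the comparison is
biparametric prostate MRI (bpMRI, no contrast agent) against
multiparametric MRI (mpMRI, with dynamic contrast-enhanced imaging) for
diagnosing clinically significant prostate cancer (csPCa, Gleason grade
group ≥ 2). Every reader interprets every case in its block under *both*
modalities, assigning suspicious lesions PI-RADS categories 3–5 and the
patient a 0–100 suspicion score. The patient-level category is the
maximum lesion category (category 2 encodes a negative exam, collapsing
PI-RADS 1–2, which readers never distinguish because only lesions with
category ≥ 3 are recorded).

Because the question is *replacement*, the hypothesis is noninferiority:
the new protocol may be worse by at most a margin δ = 0.05 on each
coprimary endpoint — the empirical AUROC of the suspicion score, and the
sensitivity and specificity of the PI-RADS ≥ 3 biopsy rule.

## Accuracy metrics

Per reader and modality the package computes:

* **Empirical AUROC** — the normalized Mann–Whitney statistic with
  half-credit for ties, equal to the trapezoidal area under the
  empirical ROC curve. Ties are real (integer scores) and receive the
  standard half-credit treatment; no jitter or smoothing is applied.
* **Sensitivity/specificity** under three positivity rules: PI-RADS ≥ 3;
  PI-RADS ≥ 4 *or* PI-RADS 3 with PSA density ≥ 0.15 ng/ml² (inclusive
  threshold); PI-RADS ≥ 4. A missing PSA density under the conditional
  rule is treated as below threshold with a warning — the conservative
  reading for a rule that adds positives on PSAd grounds.

Metrics are always computed per reader and averaged by the
Obuchowski–Rockette (OR) machinery, never pooled over readers.

## The Obuchowski–Rockette split-plot analysis

The accuracy values θ̂~ij~ (modality *i*, reader *j*) follow the OR
model θ̂~ij~ = μ + τ~i~ + R~j~ + (τR)~ij~ + ε~ij~, where the errors
ε~ij~ are equicorrelated across units through the shared cases:

* `var_error` — mean error variance of one (modality, reader) unit;
* `Cov1` — same reader, different modality;
* `Cov2` — same modality, different readers;
* `Cov3` — different reader and modality.

These are estimated by the leave-one-case-out jackknife,
Ĉov = ((n−1)/n) Σ~k~ (θ̂^(k)^ − θ̄)(θ̂′^(k)^ − θ̄′), averaged over the
qualifying unit pairs. The split-plot design partitions readers *and*
cases into blocks: readers in different blocks share no cases, so their
error covariances are structurally zero and every component is estimated
within block. Negative component means are truncated at zero before
inference (standard OR practice); raw values are kept in the output for
diagnostics.

Within block *b* with J~b~ readers the variance of the modality
difference is

Var~b~ = (2/J~b~) · (MS~TR,b~ + J~b~ · max(Cov2~b~ − Cov3~b~, 0)),

and blocks combine with reader-count weights w~b~ = J~b~/J: the pooled
difference is Σ w~b~ d~b~ (identical to the unweighted mean of
per-reader paired differences) and its variance Σ w~b~² Var~b~, blocks
being independent. Single-modality means use the analogous
(MS~R(i),b~ + J~b~·Cov2⁺~b~)/J~b~ per block.

The noninferiority test is one-sided Wald: with d the bp − mp difference
(larger metric better), p = Φ((−δ − d)/se), rejecting H₀: true
difference ≤ −δ when p < α = 0.05. Intervals are 95% Wald by default,
matching the reported analysis; `ci = "t"` substitutes Student-t
quantiles at Hillis-style Satterthwaite degrees of freedom for users who
prefer small-sample intervals. Readers and cases are both treated as
random (RRRC) — conclusions generalize to the reader and case
populations.

Degenerate situations are handled explicitly: a block with fewer than
two readers is excluded with a warning; a zero standard error with the
difference exactly at the margin reports p = 0.5 with a warning.

## Multiplicity

The three coprimary endpoints form a single Holm family by default
(`coprimary_family()` + `gatekeep()`): joint noninferiority is claimed
only if all three step-down-adjusted p-values fall below α. The
gatekeeping tree is fully configurable — families are tested only after
every parent hypothesis is rejected, and gated-off hypotheses are
reported as *not tested*, never as accepted. The adjustment itself is
delegated to `stats::p.adjust(method = "holm")`; the test suite checks
it against a from-the-definition step-down computation.

## Decision curve analysis

For a biopsy strategy with TP true and FP false positives among N
patients, the net benefit at threshold probability p~t~ is
NB = TP/N − (FP/N)·p~t~/(1−p~t~). Each reader contributes one confusion
table per strategy; curves average NB over readers, consistent with the
reader-averaged reporting of every other endpoint (the alternative —
pooling reads — is not implemented; with near-identical readers the two
coincide). The grid runs 5–30% in 0.5% steps: the published range, with
a step fine enough to locate crossing points. Derived summaries:
net reduction in interventions per 100 patients,
100·(NB − NB~all~)/(p~t~/(1−p~t~)), and the examinations needed per
additional diagnosis between two strategies, 1/ΔNB.

## The synthetic reader study

No per-read data are publicly deposited, so the package ships a
generator whose *defaults are the study conditions*. A latent suspicion
variable per read follows a Roe–Metz-style variance-component model (see
`?sim_config`); the 0–100 integer score and the PI-RADS category are
deterministic monotone transforms of the same draw, so score and
category never disagree. Reader-level components are drawn per truth
state — the Roe–Metz device that makes true accuracy vary across
readers — which yields the closed form mean AUROC
Φ(μ_eff/√(2σ²~within~)) used for calibration.

Calibration was done once, in closed form, against the published
marginals, and then verified by Monte Carlo at the stated tolerances:

* μ_sep = 1.702 and expertise deficit 0.244 put expert/nonexpert mean
  AUROC near 0.860/0.822 and the 46:16 mixture at 0.85;
* case-level variance dominates (σ²_C = 1, σ²_RC = 0.2) with small
  modality-specific terms (σ²_MC = 0.004, σ²_MR = 0.001, σ²_ε = 0.006),
  chosen so Cov1 > Cov2 > Cov3 > 0 and so the bp/mp category concordance
  sits near 91% — the pairing the published flow diagram shows;
* category cutpoints are exact quantiles of the latent mixture
  distribution at the published 49/7/18/27% category mix;
* PSA density is lognormal with class-dependent location
  (medians 0.18/0.11 ng/ml², sdlog 0.55), giving a pooled median/IQR
  near 0.13 (0.09–0.21); serum PSA is PSAd × volume for internal
  consistency.

A master seed spawns per-entity substreams (cases, case effects, one per
reader), so enlarging the reader panel never perturbs existing draws.
The generator emulates the *statistical* structure the analysis assumes
— exchangeable within-block correlation, paired modalities, expertise
strata. It does not emulate sequential-reading bias, the 5-week washout,
lesion-level spatial data, center-specific case mix, or image quality;
passing tests therefore validate the estimators under the assumed
covariance structure, not robustness to those unmodeled features.

## Problem sizes used for validation

The simulation suites use 20 readers × 100 cases × 4 blocks per
replicate — large enough for stable jackknife components (25 cases,
≥ 5 readers per block) while keeping 500-replicate batches comfortable
on one CPU: null coverage of the 95% Wald interval for the AUROC
difference and estimator bias over 500/200 replicates, and the empirical
size of the noninferiority test at the −δ boundary over 500 replicates
(`scripts/acceptance.R` recomputes all of these from scratch).
Oracle-equivalence suites (trapezoid vs Mann–Whitney AUROC, brute-force
jackknife covariances, definitional Holm) run at hand-checkable sizes.

## Known limitations

* **Boundary behavior of the Wald test.** In our boundary simulations
  the one-sided Wald test rejects somewhat above its nominal 5% level
  (while null CI coverage stays at ~95%). The mechanism is instructive:
  with the modality benefit entering as a latent shift on a *bounded*
  accuracy scale, replicates that realize a smaller average benefit also
  exhibit less benefit heterogeneity, so the estimate and its jackknife
  standard error are strongly negatively correlated, and conditioning on
  a small se inflates rejections — an oracle test with the true sd holds
  its level. The Hillis-t option reduces but does not remove the
  distortion at this study size; the effect shrinks as blocks grow.
  Users testing close to the margin with small blocks should interpret
  borderline rejections cautiously.
* The exact covariance-estimator flavor and hierarchical-tree structure
  of the original analysis are not published; jackknife estimation and a
  single Holm family are the documented defaults, both configurable.
* Sensitivity/specificity reuse the same OR machinery with the binary
  metric jackknife — valid in the OR framework, but binary metrics on
  small blocks yield granular jackknife vectors.
* Missing reads are handled only by dropping the (reader, case) pair
  from both modalities; systematic missingness is out of scope.
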