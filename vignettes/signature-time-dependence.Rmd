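---
title: "Evaluating prognostic gene signatures over follow-up time and ER status"
author: "sigsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating prognostic gene signatures over follow-up time and ER status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigsurv)
```

## The scientific question

Multi-gene prognostic signatures for breast cancer summarize an
expression profile into a scalar risk of distant metastasis. Their
published validation statistics are usually single whole-follow-up
numbers, which hides two structural facts about breast-cancer relapse:
risk biology differs between ER-positive and ER-negative disease, and
the hazard ratio associated with a signature is not constant over
follow-up — most signatures separate early relapses well and late
relapses hardly at all. `sigsurv` provides the machinery to make both
dependencies explicit: continuous scores from heterogeneous signature
families on a common cohort, population-based recalibration, and a
survival stack built around restricted follow-up intervals and
proportional-hazards diagnostics.

## Scoring model

A signature is a data object (JSON) with one of five archetypes.
Writing $x_{gs}$ for the log2 expression of gene $g$ in sample $s$:

* **centroid_subtype** — given a genes × classes centroid matrix $C$,
  compute $r_{sk} = \mathrm{cor}(x_{\cdot s}, C_{\cdot k})$ over the
  signature's genes. The subtype call is $\arg\max_k r_{sk}$ and the
  continuous risk score is the risk-of-relapse combination
  $\sum_k c_k\, r_{sk}$.
* **centroid_risk** — $d \cdot r_{s,\mathrm{ref}}$ with a declared
  reference class (for a good-prognosis centroid, direction $d = -1$, so
  resembling the good profile minimizes risk).
* **weighted_sum** — $\sum_g w_g x_{gs}$, optionally with disjoint gene
  sets per ER stratum; weights are renormalized over the genes observed
  for each sample so missing entries do not deflate the score.
* **difference_of_means** — mean(up-set) − mean(down-set), then linearly
  mapped so the cohort spans $[-1, +1]$ around its midpoint. The map is
  recorded in the score metadata; it makes the scale platform-invariant,
  which is the property that lets this family travel across studies.
* **grouped_threshold** — subtract the mean of declared reference
  (housekeeping) genes per sample, average genes within groups, clip
  group values to declared bounds, and combine as
  intercept $+ \sum_G w_G \cdot \mathrm{clip}(m_{Gs})$. This is the
  structure of unscaled recurrence-score assays.

All scores are oriented increasing-in-risk via the signature's
`risk_direction` before any downstream use.

Choices worth knowing about:

* **Correlation metric.** Published centroid classifiers disagree on the
  metric; we default to Spearman for subtype calling (robust to
  monotone distortions across platforms) and Pearson for ROR scoring
  (the ROR combination is defined on linear correlations), both
  configurable per signature.
* **Tie-breaking.** Nearest-centroid ties go to the first class in
  declared order, and any call with a winning margin below $10^{-8}$ is
  flagged ambiguous, so classifications are deterministic.
* **Mapping coverage.** Signatures rarely map completely onto another
  platform's gene universe (historically as low as ~46%). Scoring
  proceeds above a hard floor of 50% coverage, with a warning below
  80%; below the floor the low-coverage error lists the unmatched genes.
* **Duplicate probes.** When several rows map to one gene we keep the
  most variable row (preserving dynamic range); averaging is available.

## Calibration

Risk groups are assigned by fixed population proportions using
nearest-rank (type-1) empirical quantiles, so achieved counts are exact
integers and ties at a cutoff deterministically fall to the lower-risk
group. Proportions may be declared per ER stratum (e.g. "good" = lowest
30% in ER+, lowest 22% in ER−).

Standardized hazard ratios are reported per one standard deviation of
the score. The standardization context is always *exactly the sample set
entering the model being fitted* — e.g. the ER-positive subjects still
at risk in years 5–10 — not the global cohort. A global SD would shrink
or inflate per-stratum effects by the ratio of dispersions; using the
fitted subset keeps "per SD" meaningful within each analysis cell.

## Survival evaluation

* **Cox models** use `survival::coxph` partial likelihood with Efron
  ties (accurate for the moderate tie rates of yearly-scale follow-up);
  Breslow is available. Cohort adjustment is done by stratified
  baselines (`strata(cohort)`), which adjusts for baseline differences
  without forcing proportional cohort effects.
* **C-index** is Harrell's concordance over usable pairs (the earlier
  time has an event, or tied times with exactly one event); score ties
  count ½. The default CI is the asymptotic normal interval over the
  usable-pair count, with a seeded bootstrap as an alternative. The
  implementation is vectorized pair counting; tests verify exact
  equality with brute-force enumeration and with
  `survival::concordance`.
* **PVE** is $1 - \exp(-G/n)$ with $G$ the likelihood-ratio statistic
  against the null model — a deliberately simple, documented estimator
  of explained variation; the result tables record that this is the
  estimator used.
* **The PH diagnostic** is the Grambsch–Therneau test: scaled Schoenfeld
  residuals correlated with transformed event time, reporting both ρ and
  the χ² p-value (current `survival::cox.zph` no longer reports ρ,
  which is the quantity of interest here: negative ρ means prognostic
  power decays with follow-up). The default time transform is the
  left-continuous 1 − KM(t) at event times; identity and rank are
  available.
* **Interval analyses** restrict the data to half-open windows
  $[a, b)$: subjects failing or lost before $a$ are excluded, events and
  censorings inside the window keep their original time, and subjects
  still at risk at $b$ are censored there. An event exactly at $b$
  belongs to the next interval; this convention makes the windows a
  partition — every event is counted in exactly one interval, which the
  tests assert structurally. Because all subjects in a window share the
  same entry time, an ordinary Cox fit on the restricted data equals the
  left-truncated analysis. Default windows are 0–5, 5–10, >10 years. A
  cell that cannot be fitted (no events, constant score) reports the
  reason rather than disappearing.
* **Aalen additive regression** accumulates least-squares increments of
  the additive hazard model at each event time, with variance
  accumulated from squared increments and pointwise 95% bands. A
  time-constant effect gives a straight cumulative line; an early-only
  effect rises and then flattens. Accumulation stops at the first
  singular design (e.g. risk set of one) and records the truncation
  time.
* **Multivariate models** encode tumor size as ordered categories (pT1
  reference), node as binary (negative reference) and grade as
  categories (grade 1 reference), and fit four declared sets: signature
  alone, +size, +grade, +size+node+grade. Unknown categories drop a
  sample from the affected models only.

## The synthetic cohort

`simulationConfig()` declares a complete generative model; its defaults
are the study conditions the package is designed around:

| parameter | default | rationale |
|---|---|---|
| cohort size | 912 (75.9% ER+) | typical pooled microarray meta-cohort with DMFS follow-up |
| subtypes | 5, with ER-stratum-specific frequencies | luminal-dominated ER+, basal/HER2-dominated ER− |
| shared-factor loadings | 0.8–0.9 per signature | gives score–score correlations ≈ 0.6–0.8, the empirically typical range |
| signature-specific SD | 0.45 | with loading 0.9 yields ρ ≈ 0.8 between two such scores (factor-model closed form $l_1 l_2 / \sqrt{(l_1^2+\sigma^2)(l_2^2+\sigma^2)}$) |
| gene noise SD | 0.5 | per-gene measurement noise on log2 scale |
| ER+ hazard | baseline 0.035/yr; β(t) = log 2 on [0,5), 0 after, on the standardized proliferation factor | strong early effect that vanishes late |
| ER− hazard | baseline 0.065/yr; β(t) = log 1.5 on [0,5), 0 after, on the independent hypoxia factor | ER− risk driven by distinct (stress-response-like) biology |
| censoring | exponential rate 0.06/yr plus administrative cutoff at 15 yr | realistic loss to follow-up and study horizon |
| grade / size | quantile cuts (1/3, 2/3) and (0.5, 0.88) of the proliferation factor | makes grade and size partial mediators, so adjusting for them attenuates signature effects |

One hypoxia-like signature loads on the independent factor; the other
eight load on shared proliferation. Survival times are drawn exactly by
piecewise-exponential inversion, which matches the interval-wise
analysis model; `expectedEventCount()` gives the closed-form expected
event count (per-interval integration against the censoring survival,
averaged over the driver by quadrature) and simulations are checked
against it to 3 binomial SDs. All randomness flows from one seed via
fixed per-component sub-streams (latents, expression, survival,
censoring, covariates), so components are independently reproducible.

What the generator deliberately does **not** emulate: platform/batch
artifacts, probe-level effects, correlated measurement noise across
genes, copy-number structure, and cross-platform annotation loss.
Consequences worth stating: subtype calls on the synthetic data are
nearly perfect, so the two centroid callers agree almost completely
(κ ≈ 1), whereas real cross-platform centroid classifiers agree only
moderately — a passing κ pipeline test shows the statistic is computed
correctly, not that real-world concordance is reproduced. Likewise the
synthetic score–score correlation matrix is smoother than a real one.

## Numerical and degenerate-input policy

Missing expression is handled pairwise in correlations and by weight
renormalization in sums; sample/centroid pairs sharing fewer than 3
observed genes yield a missing correlation; subjects with missing
scores, times or strata are dropped from exactly the affected analysis.
Degenerate inputs error early and specifically: constant covariates,
zero events, zero context SD, identical scores in a calibration context,
non-tiling intervals. The receptor-status imputation fits an
equal-variance two-component Gaussian mixture to a marker gene (ESR1 or
ERBB2) and calls positive at posterior > 0.5 on the higher-mean
component; if the components collapse (separation < 0.1 pooled SD) it
falls back to a median split and flags the result.

## Design decisions that were genuinely open

* The evaluation stack is organized Bioconductor-style: the cohort is a
  `SummarizedExperiment` subclass, signatures and score tables are S4
  with validity, while statistical results are plain data frames —
  mirroring how survival-analysis results are consumed downstream.
* The command-line layer is a thin script over `validateConfig()` /
  `runPipeline()` / `simulateCohortFiles()` with `simulate`, `validate`
  and `run` subcommands. Finer-grained stage subcommands were dropped:
  in an R package the stages are already independently invokable as
  functions, and the pipeline remains a pure function of
  (inputs, config, seed).
* Test and simulation problem sizes (e.g. 100 Cox replicates at
  n = 2000, 1000 PH null replicates at n = 300, one 6000-sample
  end-to-end cohort) were chosen as the smallest designs at which the
  checked properties have comfortable statistical margins.

## Limitations

Competing risks, time-dependent covariates beyond interval restriction,
and penalized models are out of scope. The shipped signature definitions
are synthetic exemplars of each archetype — the engine implements the
scoring algorithms, but reproducing a commercial assay requires its
published coefficients as definition data. PVE here is the
likelihood-ratio-based estimator stated above, not interchangeable with
other explained-variation measures. Interval hazard ratios in small
strata (tens of events) carry wide intervals; single-cohort draws can
and do miss a true moderate effect, which is precisely the uncertainty
the interval tables quantify.
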