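# sigsurv

Multi-gene prognostic signature scoring and time-dependent survival
evaluation for breast cancer cohorts.

## The problem

Nine widely used breast-cancer prognostic signatures — the two
nearest-centroid subtype classifiers with their risk-of-relapse (ROR-S)
scores, the 70-gene and Wound-Response centroid-correlation scores, the
ER-stratified 76-gene and the Hypoxia weighted sums, the Genomic Grade
Index difference-of-means, and the unscaled Recurrence Score and
EndoPredict grouped-threshold scores — all map an expression profile to a
scalar risk, but their prognostic power for distant-metastasis-free
survival (DMFS) is not constant: it depends strongly on follow-up time
and on ER status. `sigsurv` implements the full evaluation pipeline
needed to quantify that dependence:

- **Scoring.** Five scoring archetypes cover the signature families.
  A signature is *data*, not code: a JSON document
  (genes, weights, groups, centroids, ROR coefficients, risk direction,
  calibration proportions) validated against
  `inst/extdata/signature-schema.json`. All scores are oriented so higher
  = higher risk. For a centroid archetype the score of sample *x* is
  built from cor(*x*, centroid<sub>k</sub>) over the signature's genes;
  ROR-S is Σ<sub>k</sub> c<sub>k</sub>·cor(*x*, centroid<sub>k</sub>).
- **Calibration.** Population-based risk groups: a fixed proportion of
  the cohort per group via nearest-rank quantile cutoffs, optionally per
  ER stratum (e.g. lowest 30% in ER+ and 22% in ER− as "good" prognosis;
  51%/22%/27% low/intermediate/high for the recurrence-score family).
- **Evaluation.** Kaplan–Meier curves and log-rank tests per risk group;
  Harrell's C-index and the proportion of variation explained
  PVE = 1 − exp(−G/n); standardized hazard ratios (per 1 SD of score)
  from Cox models; Grambsch–Therneau proportional-hazards diagnostics
  (correlation ρ of scaled Schoenfeld residuals with transformed event
  time); hazard ratios per follow-up interval (0–5, 5–10, >10 years)
  and ER stratum, with subjects failing before an interval excluded and
  subjects at risk at its end censored there; Aalen additive-hazards
  cumulative regression; multivariate Cox models combining a signature
  with tumor size, node status and histological grade.
- **Agreement.** Pairwise score correlations, subtype confusion matrices
  and Cohen's κ between centroid classifiers.
- **Synthetic cohorts.** A seeded generator produces expression +
  clinical data with the statistical structure the analysis assumes —
  two ER strata with different risk biology, signature scores driven by a
  shared latent proliferation factor (plus an independent hypoxia-like
  factor), piecewise-constant log-hazard effects (strong before year 5,
  null after) and independent censoring — with full ground truth, so
  every stage is testable without access to patient data.

## Worked example

```r
library(sigsurv)

cfg <- simulationConfig(n_samples = 400, seed = 42)
sim <- simulateCohort(cfg)
sim$cohort
#> SignatureCohort: 536 genes x 400 samples
#>   events: 119 / 400 with follow-up
#>   ER+: 304  ER-: 96

st <- scoreAll(sim$cohort, sim$signatures)
st
#> ScoreTable: 400 samples x 9 signatures
#>   status: 9/9 scored
#>   subtype calls: intrinsicLike, pam50Like

score <- riskScores(st)[, "ggiLike"]
cx <- coxFit(standardizeScores(score),
             sim$clinical$time_years, sim$clinical$event)
cx
#> Cox model (efron ties): n = 400, events = 119
#>   term  beta     se   hr lower upper      p
#> 1    x 0.192 0.0942 1.21  1.01  1.46 0.0419

intervalEffects(score, sim$clinical)[, 1:8]
#>   interval  stratum n_risk n_event    hr lower upper        p
#> 1   0-5 yr negative     96      19 1.349 0.842  2.16 2.13e-01
#> 2  5-10 yr negative     50      13 0.835 0.467  1.49 5.42e-01
#> 3   >10 yr negative     23       4 0.733 0.253  2.13 5.68e-01
#> 4   0-5 yr positive    304      43 1.990 1.460  2.71 1.33e-05
#> 5  5-10 yr positive    192      26 0.721 0.489  1.06 9.81e-02
#> 6   >10 yr positive    110      14 0.561 0.312  1.01 5.26e-02

phTest(cx)
#>   term    rho chisq        p
#> 1    x -0.359  18.2 1.98e-05
```

Read: over the whole follow-up the standardized HR of this
difference-of-means score is a modest 1.21, but the interval analysis
shows why — a strong early ER-positive effect (HR 1.99 in years 0–5)
that disappears later, and little power in the ER-negative stratum. The
negative Schoenfeld ρ (−0.36, p < 0.0001) flags exactly this decay of
prognostic power with follow-up time.

The same analysis runs as a pipeline over TSV/JSON inputs
(`runPipeline()` with a YAML config, or the thin CLI in
`inst/cli/sigsurv.R` with `simulate`/`validate`/`run` subcommands),
writing scores, risk groups, agreement matrices, performance, interval,
PH, multivariate, KM and Aalen tables plus seeded run metadata to an
output directory.

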