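---
title: "Methods: trial-based cost-utility analysis with DRG costing and multiple imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thoracoCUA)
```

`thoracoCUA` implements the medico-economic analysis of a two-arm surgical
randomised trial — video-assisted thoracoscopic surgery (VATS) versus open
thoracotomy for early-stage lung cancer — from the hospital perspective,
together with a synthetic-trial generator that reproduces the statistical
structure the analysis assumes. This vignette is the package's account of
the science: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic data do and do not establish.

## Hospital costing

Costs cover three resource groups: the initial surgical stay,
re-hospitalisations for post-surgical complications, and rehabilitation
admissions, all valued as production costs in 2018 euros (the
`inflate_cost()` helper updates between price years by the ratio of a
consumer-price index; the bundled health-services series is synthetic and
labelled as such).

**Initial stays** use the *adjusted-DRG* method. Every initial stay shares
one DRG root ("major surgery on the thorax") and differs only by severity
level 1–4, mapped to codes 04C021–04C024. The severity rule is a packaged
table-driven default — one level added per major complication,
re-intervention, or prolonged stay (LOS beyond the arm mean + 2 SD), capped
at 4 — because classification-authority rules are not reducible to a single
formula; users with real grouper output can supply the level directly. The
DRG's operating-room component is replaced by the theatre cost measured by
micro-costing (defaults €3,870.49 for VATS, €2,455.58 for thoracotomy —
configuration constants, not re-estimated here), and the remainder of the
DRG cost is converted to a daily cost via the national mean LOS and
weighted by the patient's own LOS:

cost = theatre(arm) + LOS × (total − OR) / national_mean_LOS.

**Re-hospitalisations** are gross-costed at their DRG's catalog cost; a
reason→DRG rule table stands in for case-by-case grouping, and a stay whose
reason has no rule is *uncostable*: it is excluded from cost sums with a
warning rather than failing the pipeline, and the affected window component
is flagged so the imputation stage can treat it as missing. LOS-prorating
of re-hospitalisation costs is available behind a flag
(`prorate_rehosp`) since gross versus prorated costing is a genuine
methodological fork; gross costing is the default.

**Rehabilitation stays** all map to one DRG (0403B1) with a flat cost of
€6,222.20 — the one catalog value that is a published figure rather than a
synthetic calibration; the 04C02x rows of the shipped catalog are synthetic,
chosen so that the implied daily cost (≈ €946/day) makes simulated
initial-stay means land near €10,670 (VATS) and €9,213 (thoracotomy).

Monetary arithmetic is kept at cent precision (rounding to cents at each
stay-cost computation; sums of cent amounts are exact in doubles), and ICERs
are rounded to whole euros only at reporting (`icer_reported()`).

**Windows.** Day offsets are integers with surgery at day 0. Cumulative
30-day cost = initial + events admitted in the half-open window (initial
discharge, d30 visit]; the 3-month cost adds (d30 visit, m3 visit]. When a
visit is undated or missing, the nominal day (30 or 91) bounds the window.
Monotonicity (3-month ≥ 30-day) holds by construction and is asserted in
the tests.

## Utilities and QALYs

EQ-5D-3L states (five dimensions, levels 1–3) are scored by an additive
value set: utility = 1 − constant·[any dysfunction] − per-level decrements −
N3·[any level 3]. The bundled default is the UK TTO tariff — fully
published coefficients, floor −0.594 — shipped as a CSV and swappable,
since the trial context does not pin a national tariff; all utility-level
results are therefore tariff-conditional, and the generator's calibration
targets are means, not exact reproductions.

The per-patient QALY at a horizon is the trapezoidal area under the
utility-versus-day curve divided by the horizon length — a time-weighted
average utility. This scale choice is deliberate: reported "final QALYs" at
30 days of magnitude ≈ 0.67–0.74 are incompatible with year-denominated
area over 30 days (which is bounded by 30/365 ≈ 0.08) and consistent with a
time-weighted average; a year-scaled variant is available via
`qaly_auc(..., year_scale = TRUE)`. Two further conventions: the
pre-operative questionnaire is anchored at day 0 (no pre-operative offset
is available), and the trajectory is extended flat from the final
observation up to the nominal horizon (or truncated there), so jittered
visit dates perturb the weighting but not the support. The 30-day horizon
requires the preop/d3/d30 utilities, the 3-month horizon adds m3; no
discounting is applied at horizons under a year.

## Comparative analysis

The complete-case cascade excludes, in order and with each patient
attributed to the first failing criterion: death before the visit,
off-window visits, undated visits, missing EQ-5D; the 3-month cascade
starts from the 30-day complete cases. "Much earlier or later" than the
nominal visit day is operationalised as ±14 days (configurable
`window_tol`) — the criterion is stated in the source methodology without a
tolerance, so the default is a round fortnight.

Cost and QALY differentials use Student's t-test with pooled variance
(Welch behind a flag); mortality is contrasted by a Wald risk difference
and a single-covariate logistic odds ratio. When mortality does not differ
at the 5% level the cost comparison is labelled a cost-minimisation
analysis — a labelling rule, not a computational gate. The ICER divides the
differentials computed on the same included set and is quadrant-classified
on the cost-utility plane.

## Bootstrap and acceptability

Uncertainty uses a non-parametric bootstrap stratified by arm with original
arm sizes preserved — the standard design-respecting choice for two-arm
trial CEA — resampling patients (cost and effect paired) and recomputing
the mean differentials, B = 10,000 by default. All resampling indices are
drawn as one block from the root seed before any replicate is evaluated, so
results are independent of evaluation order. The ICER interval is the
percentile interval of the per-replicate ratios; replicates with a zero
effect differential are dropped with their count reported, and negative
ratios are kept in numeric order — the known caveat of percentile intervals
on ratios that cross quadrants, which is why the acceptability curve is the
preferred summary.

The acceptability curve defaults to the net-monetary-benefit rule,
P(λ·ΔE − ΔC > 0), which orders all quadrants correctly; the literal "ICER
below λ" ratio rule is provided as an option because published figure
captions often phrase the curve that way. Both rules agree when every
replicate is in the northeast quadrant, and replicates with ΔE exactly 0
count as not acceptable under both (a measure-zero deterministic
tie-break). The default λ grid runs 0–100,000 €/QALY in steps of 1,000 and
contains the conventional €25,000 reference threshold. Quadrant shares
assign on-axis replicates to the weakly-positive side so the four fractions
always sum to one.

## Multiple imputation

The sensitivity analysis imputes the 20 EQ-5D item columns (5 dimensions ×
4 timepoints) and any missing cost components on patients alive and in
follow-up at 3 months, with m = 10 datasets. The chained-equations engine
is implemented in the package: predictive mean matching (k = 5 donors,
Bayesian parameter draw) for continuous costs, and sequential
continuation-ratio logistic draws — P(level ≥ 2), then P(level 3 | ≥ 2),
with coefficients drawn from their asymptotic normal — for the 3-level
items, which is a multinomial-type draw that is robust and fast at three
levels; degenerate fits fall back to marginal draws. Chains burn in for 10
cycles visiting variables in increasing-missingness order; per-variable
chain means are returned as a trace for convergence inspection (no formal
test is applied). Observed cells are never altered, and imputed items are
re-scored to utilities — utilities are never imputed directly.

The default predictor set mirrors the trial's imputation model: age, sex,
performance status, smoking status, BMI, all items at all timepoints, and
the hospital cost components (split by window so imputed costs can be
cumulated per horizon). That set omits the randomisation arm, which makes
the imputation model uncongenial with an analysis model that estimates an
arm effect and attenuates the imputed differential; the package keeps the
omission as the default for fidelity to the trial's stated model, but the
recovery experiments in the test suite add `arm` to the predictors, the
congenial choice when the estimand is the arm contrast.

QALYs on imputed data use nominal visit days (30/91), since undated visits
are among the reasons data are missing. Pooling follows Rubin's rules for
the point estimates (pooled ICER = ratio of pooled differentials);
within/between variance components are reported. For the bootstrap the
nesting is within-imputation by default — each completed dataset is
resampled B/m times and the replicate clouds pooled for the percentile
interval — with re-imputation inside each bootstrap resample available
behind a flag for small B; which nesting the source analyses used is not
knowable, and the within-imputation form is the cheaper standard practice.

## The synthetic-trial generator

The generator's defaults are the study conditions: two arms of 130 patients
in 10 centres, 1:1 permuted blocks of 12 stratified by centre; per-arm ×
per-timepoint mean utilities (0.83/0.66/0.80/0.79 VATS,
0.78/0.58/0.74/0.76 thoracotomy, common SD 0.25); initial-stay LOS gamma
with mean/SD 7.20/3.72 and 7.13/2.85 days; re-hospitalisation
probabilities 4.58%/8.39% (VATS, by window) and 3.13%/2.34% (thoracotomy);
rehabilitation 6.87%/3.82% and 6.25%/0%; 30-day death probabilities
0.76%/0.78% with an additional 2% per arm to 3 months (90-day mortality
after lobectomy is typically 2–3%; the source reports survival percentages
too censoring-distorted to invert); per-timepoint record missingness
10%/17%/15%/27% (the average of the two arms' completion counts).

Three generator mechanics deserve note. (1) *Utility inversion*: a latent
normal utility is mapped to the EQ-5D state with the nearest tariff value
(ties to the lexicographically smallest state). Discretisation against a
finite tariff support shifts the scored mean away from the latent mean, so
`calibrate_latent_mean()` solves for the latent mean whose *scored*
expectation equals the target exactly, using the midpoint partition of the
tariff support — the calibration tests then only carry sampling error.
(2) *LOS*: gamma rounded up to whole days with minimum 1; the gamma mean is
shifted down half a day so the rounded variable matches the configured
mean. (3) *Visit realism*: d30/m3 visit days jitter (SD 4 days), 3% of
visits land far off-window and 3% are undated, and deaths censor later
visits and stays — these choices exist to give the exclusion cascade and
the windowing logic real work, and are configurable.

Missingness is MCAR by default (independent per-timepoint record deletion);
the MAR variant makes deletion logistic in arm and pre-operative utility
with the intercept recalibrated to preserve the marginal rate, so the
imputation stage can be exercised under a mechanism where complete-case
analysis is biased. Which mechanism produced the motivating trial's missing
data is unknowable; neither variant claims fidelity.

**What passing tests show — and don't.** The generator draws each
timepoint's missingness independently, so four-timepoint completeness
compounds to ≈ 54% where real questionnaire missingness is strongly
patient-correlated (real complete-case counts are higher); its utilities
are cross-sectionally independent draws around arm/time means rather than
patient-level trajectories; and its event costs are table-driven. Tests on
synthetic data therefore validate the *machinery* — calibration,
windowing, exclusion order, bootstrap calibration, imputation recovery —
not the clinical or economic magnitudes of any real trial, which enter only
as calibration targets and worked-example inputs.

## Numerical and reproducibility choices

Fixed-seed determinism is end-to-end: the trial config seed drives
generation (sub-stages use fixed offsets), the bootstrap draws its index
block from its own seed, imputation chains get seeds from one root, and
`run_pipeline()` derives all stage seeds from a single root seed — two runs
with the same root produce byte-identical `summary.json`. Percentile
intervals use the default type-7 quantile. Degenerate inputs are handled
deterministically: zero-variance groups have no t-test (reported as NA in
tables), zero-effect differentials give an undefined ICER ("axis"
quadrant), an all-identical cohort collapses every bootstrap replicate to
the point estimate, and a variable that is 100% missing is refused rather
than imputed.

Problem sizes in the shipped test suite were chosen to exercise asymptotics
while staying desk-scale: calibration at n = 130/arm, law-of-large-numbers
checks at n = 5,000, bootstrap coverage over 200 simulated trials of
n = 260 with B = 1,000, imputation recovery over 50 seeds at m = 5 chains ×
5 cycles, and two full B = 10,000 / m = 10 pipeline runs for the
determinism check.

## Known limitations

- The severity-level rule and the re-hospitalisation reason→DRG table are
  simplified stand-ins for national grouper logic.
- The tariff actually used by the motivating trial is unstated; bundled-UK
  results are tariff-conditional.
- Percentile (not Fieller or BCa) intervals only; ratio intervals crossing
  quadrants are reported but the CEAC should be preferred.
- Rubin variance components are reported but the bootstrap CI pools
  replicate clouds across imputations rather than combining variances
  analytically; with m = 10 and B = 10,000 the practical difference is
  small.
- The micro-costed theatre costs are consumed as constants; no uncertainty
  in them is propagated.
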