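---
title: "Methods: protein risk scans, penalized prediction and simulation-based power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein risk scans, penalized prediction and simulation-based power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protscan)
```

This vignette is the package's own account of its models and of the
choices made where the underlying methodology left the design open. The
setting is a prospective screening cohort in which plasma proteins were
measured with a Proximity Extension Assay (NPX units, log2-like) in
two recruitment centres, incident cases accrued over a 36-month horizon,
and controls were selected by median matching on age at blood draw. The
package provides the full analytical chain for that setting — synthetic
cohort generation, protein QC and normalization, per-protein
covariate-adjusted Cox scans, penalized risk prediction, and
simulation-based post hoc power — as testable, seeded components.

## The synthetic cohort generator

`generate_cohort()` simulates a *pool* of women, assigns events under a
proportional-hazards model, and then draws the analyzed case-control
sample from the pool, mirroring how a matched sample is nested in a real
cohort.

**Covariates.** Age at blood draw is Normal(58.5, 9.6²) years (truncated
far in the tails), BMI Normal(25.4, 4.2²) kg/m², percent mammographic
density Beta(1.8, 5.4) (mean 0.25), plasma storage age Normal(7.8, 0.7²)
years, the 313-variant polygenic score Normal(−0.05, 0.30²), and the
binary covariates Bernoulli at their documented baseline frequencies.
Menopause status is derived from age against a latent Normal(53, 4²)
menopause age, which both couples it to age and yields ~70%
postmenopausal at the default age distribution.

**Proteins.** Protein *p* for woman *i* is
$x_{ip} = \mu_p + \lambda_p' f_i + s_p \cdot \mathbb{1}[\text{centre B}] + \varepsilon_{ip}$
with $k = 5$ standard-normal latent factors, loadings
$\lambda \sim N(0, 0.2^2)$, residual noise $\varepsilon \sim N(0, 0.5^2)$
NPX, and a per-protein centre-B shift with spread 0.5 NPX. The loading
and noise scales were chosen together so that (a) per-protein total SD is
≈ 0.67 log2 units, a realistic inter-individual spread for PEA panels,
and (b) the centre shift is large enough *relative to the correlated
biological variance* that unsupervised clustering of raw NPX separates
the centres, as such batch structure does in practice. With loadings much
above 0.2 the factor-driven distance variance swamps the fixed shift and
no linkage recovers the centres, which would defeat the purpose of the
clustering diagnostic; Ward linkage is the default for the same reason.

**Detection limits and missingness.** Per-protein LODs are placed at the
quantile of the centre-A marginal that gives a mean below-LOD fraction of
0.12; a single offset on the centre-B shifts is then solved by root
finding so centre B averages 0.14. Measurements below LOD are *retained*
(as NPX pipelines do) and only counted into the per-participant
below-LOD fraction, which enters the adjustment set. Missingness is
completely at random, 2% per centre by default; the mechanism is a
modelling convenience, not a claim about assay behaviour.

**Outcomes and sampling.** The hazard is
$\lambda_0 \, \exp\!\big(\sum_p \beta_p z_{ip} + \gamma' c_i\big)$ with
$z$ the protein in per-SD units of its *biological* (pre-batch-shift)
signal — a technical shift should shift measurements, not risk — and
exponential event times (Weibull shape exposed) censored at 36 months,
rounded up to whole months. The baseline hazard is calibrated by root
finding so that the expected number of pool events is
`oversample × n_cases`, with the pool sized at
`oversample × (n_cases + n_controls)`. Cases and controls are then kept
at the *same* rate 1/oversample, which makes the analyzed sample an
(approximately) outcome-independent random subsample of a cohort, so the
Cox fit on the case-control set recovers the injected per-SD log hazard
ratio without material bias (measured |bias| < 0.01 at β = 0.25 and 0.5).
The default oversample of 1.3 (1.5 inside the power simulations) also
leaves enough non-case slack for matching. Default covariate effects are
mild for age (0.003/y) and menopause (0.05): both shift the age
distribution of the *matched* sample upward through case selection, and
the defaults keep the sample's moments at the documented baseline values
while retaining informative risk factors (polygenic score 1.5 per unit,
density 1.2 per unit fraction, family history 0.45) for the prediction
analyses.

**Median matching.** Controls are selected by rejection sampling —
uniform candidate sets, accept the first whose age median is within 0.5 y
of the case median — with a greedy swap fallback that trades controls
from the heavy side for unused candidates on the light side, and a
sliding-window construction over the sorted candidates as a last resort
for small pools. Inside the generator the rejection budget is kept short
(200 draws): with an age-linked hazard the case median sits above the
candidate median, a uniform draw essentially never lands within
tolerance, and the deterministic fallback is both cheap and reliable. In
the power simulations, a replicate whose case and candidate medians are
mutually unreachable (a ~1% event at the exploratory design size) is
regenerated from a derived seed — conditioning on matchability, exactly
as a matched study does by construction.

**Seeding.** One master seed drives derived streams (covariates, factors,
one per protein, events, selection, matching, tumour markers), so output
is bit-reproducible and adding proteins does not perturb earlier draws.

## QC and normalization

`filter_proteins()` implements both exclusion rules: the per-centre rule
(drop when missing > 10% in *any* centre; targeted panels) and the
overall rule (drop when missing > 50% across all samples; exploratory
panel), plus vendor-style QC warnings. The rank-based inverse normal
transformation replaces each protein's values within each centre by
$\Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with average ranks for ties
and the symmetric offset $c = 0.5$ (Blom's $3/8$ selectable). The
symmetric offset makes the per-centre mean exactly zero, which is the
property the centre-shift removal relies on; the output depends on the
data only through ranks. A protein constant within a centre has no rank
information and is set to zero and flagged. PCA mean-imputes missing
values per protein within centre, orders components by explained
variance, and fixes each component's sign so its largest-magnitude
loading is positive. The clustering diagnostic mean-imputes per protein
overall (a neutral fill that cannot create group structure); restricting
it to complete proteins is not viable since at 2% missingness and
hundreds of samples no protein is complete.

## The association scan

Each protein is standardized to unit SD among its complete cases (≈ 1
after INT; applied anyway for exactness) and fitted with the full
adjustment set by Cox partial likelihood with Efron's tie correction —
ties are common at monthly resolution, and Efron is accurate even with
~20 tied events per month. Inside `run_scan()` the fits go through the
survival package's fitting routine directly with a prebuilt covariate
design matrix; this is numerically identical to the formula interface
(asserted in the tests) and roughly four times faster, which is what
makes hundreds of replicate scans practical. Records are flagged rather
than dropped on non-convergence; a diverging *nuisance* covariate (e.g. a
rare binary indicator with no events in one level) is not flagged, since
the exposure's Wald inference is unaffected. Bonferroni and BH
adjustments come from `p.adjust`; principal-component exposures form
their own multiplicity family of size k. Under the global null the scan's
p-values are uniform (Kolmogorov–Smirnov checked on > 1000 pooled
p-values from factor-free cohorts, where pooling independence holds).

Case subsets for stratified scans keep all controls; strata with fewer
than 10 case events are skipped and reported. The case-only test is a
logistic regression of the case subtype on the protein with
case-applicable covariates; the covariate set there is a judgement call,
and the package uses the adjustment-set covariates that are defined for
cases.

## Penalized prediction

The prediction model is L1-penalized *logistic* regression on incident
case status — AUC is the reported metric and the natural loss for it; a
penalized Cox variant is out of scope. The objective is
$\tfrac{1}{n}\,\text{NLL} + \lambda \sum_j |\beta_j^{\text{protein}}|$
with the intercept and all baseline covariates (age, BMI, percent
density, menopause status, polygenic score, family history) unpenalized.
Fits use glmnet with `penalty.factor` 0/1; glmnet internally rescales the
penalty factors to sum to the number of variables, so λ is pre-scaled to
keep the stated objective exact (the duplicate-feature degeneracy test
would catch any drift here). The λ grid is 50 log-spaced points from
$\lambda_{\max}$ — the smallest penalty that zeroes every protein, computed
from baseline-model residuals — down to $0.001\,\lambda_{\max}$. Cross-
validation is fivefold, stratified by case status and centre; protein
medians and SDs for imputation and scaling are learned on training folds
only. The baseline AUC is cross-validated identically with no protein
features. One caution the tests encode: a *single* null dataset carries
chance protein-outcome correlations shared by training and held-out
folds, so null behaviour must be judged across data realizations, not
folds.

## Simulation-based power

`estimate_power()` regenerates the full design per replicate — cohort,
matching, INT, adjusted Cox fit — with the effect injected into one
protein, and counts Wald p-values below α/m; the family size enters only
through the threshold, matching a per-protein power question. Replicates
share nothing but the master seed, and the same replicate streams are
reused across effect sizes (common random numbers), which makes the
power estimate monotone in β and the 80% bisection well-behaved; the
bisection brackets log HR over [0, 1.5] to a width of 0.01.

The Schoenfeld approximation
$\Phi(|\beta|\sqrt{d} - z_{1-\alpha^*/2})$ is implemented as an
independent cross-check. Two non-collapsibility facts shape how it is
used. First, *adjusting* for real risk factors inflates the per-SD SE
(measured ≈ 1.25× at the targeted design), so adjusted simulated power
sits below the closed form at mid-range effects — the headline power
numbers use the adjusted model regardless, because that is the analysis
whose power is in question. Second, an *unadjusted* fit of a
covariate-driven hazard estimates an attenuated marginal HR, so it does
not match the formula either. The formula's premises — unit-variance
exposure, no covariates — are honoured by the unadjusted mode
(`design_spec(adjusted = FALSE)`), which removes covariate effects from
generation and analysis alike; in that mode simulation and closed form
agree within Monte-Carlo error at every grid point, which validates the
simulation machinery itself.

Typical results under the shipped defaults: power ≈ 97% at HR 1.28 per
SD for the targeted design (796 cases / 781 controls, m = 163), ≈ 100%
at HR 1.74 for the exploratory design (303 / 294, m = 2204), detectable
HRs at 80% power ≈ 1.23 and ≈ 1.45 — the adjusted-model SE inflation is
why these sit below the naive closed-form landmarks. These statements are
recomputed, not stored: `scripts/acceptance.R` regenerates them from
scratch for any seed.

## Problem sizes, tolerances, degenerate inputs

The routine test suite runs reduced designs: 150 replicates for the
power-at-claim checks, 60 per bisection evaluation at a 0.02 bracket,
20 global-null scans, 100 replicates per recovery check; the acceptance
script uses 400 power replicates, 100 per bisection step at the
specified 0.01 bracket, and 350 null scans. Cox iterations stop at a
1e-10 partial-likelihood tolerance (100 iterations max); |β| > 20 is
treated as separation. glmnet convergence thresholds are 1e-10–1e-12
with the KKT conditions of the stated objective re-checked explicitly.
Degenerate inputs are either errors with actionable messages (empty
matrices, zero-variance exposures, unreachable matching targets reported
with the best achieved gap, infeasible case counts reported with the
achieved event fraction) or flags (separation, non-convergence, constant
proteins under INT).

## What the generator does and does not emulate

It emulates the *design*: sample sizes, matched structure, covariate
moments, centre batch shifts, below-LOD rates, correlated panels, a
proportional-hazards outcome. It does not emulate assay chemistry, plate
or bridging effects, informative missingness, non-proportional hazards,
measurement-error structure correlated with covariates, or real protein
biology (true effects are whatever the effect specification injects).
Consequently, passing tests demonstrate that the *analytical machinery*
is correct and well-calibrated under the stated model — they do not
certify behaviour under violations of it, and power statements inherit
the proportional-hazards and MCAR assumptions. The per-protein power
question also ignores the winner's curse: an effect-size estimate
*selected* for significance overstates the truth, which is precisely why
post hoc power at prespecified effect sizes, not observed ones, is the
quantity computed here.
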