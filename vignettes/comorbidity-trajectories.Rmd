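---
title: "Modelling comorbidity trajectories in obesity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling comorbidity trajectories in obesity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbiditrail)
```

## The problem

Obese adults accumulate chronic conditions in sequences, not at random.
`morbiditrail` asks two questions of a longitudinal health-survey panel:
which disease systems co-occur most strongly in cross-section, and how fast
do people progress from health, through single and dual disease states, to
the triple-comorbidity state formed by the strongest trio? It answers the
first with Apriori association-rule mining over seven disease systems
(cardiovascular CVD, metabolic MTD, respiratory RPD, skeletal-muscular SMD,
neurological NRD, mental disorders MD, cancer CC), and the second with a
nine-state continuous-time Markov model fitted to interval-censored panel
data. Because the survey data that motivated this design are
access-restricted, the package ships a synthetic-cohort generator with
known ground truth; every stage of the pipeline is validated against that
truth or against independent closed-form oracles.

## The nine-state progression model

States: 1 healthy; 2 at least one non-trio disease but no trio component;
3/4/5 exactly one trio component (first/second/third); 6/7/8 the dual
combinations first+second, first+third, second+third; 9 all three —
absorbing. Allowed transitions are single-acquisition steps only:
1→{2,3,4,5}, 2→{3,4,5}, from a single state only to dual states containing
it, and from each dual state to 9 (16 directed edges). Participants holding
a non-trio disease alongside trio components are assigned by their trio
subset alone; state 2 applies only when no trio component is present.
Without that rule the "single disease only" states would be unreachable for
most of a realistic cohort and the comparisons that start from them would
be undefined.

The chain is time-homogeneous with generator \(Q\): off-diagonal entries
are per-year transition intensities on allowed edges, rows sum to zero.
States are observed only at survey waves, so the likelihood of an observed
pair \((s_0, s_1)\) separated by \(\Delta t\) years is the matrix-exponential
entry \([e^{Q\Delta t}]_{s_0 s_1}\), and the full log-likelihood is the sum
over consecutive observation pairs. This is the standard panel-data
(interval-censored) multi-state formulation: it reports instantaneous
transition intensities even though the data are discrete wave snapshots,
and it is what reconciles "discrete-time observation" with
"continuous-time progression". Disease indicators are carried forward
within participant before state assignment (conditions are reported as
ever-diagnosed and the model has no backward arrows), so apparent
remissions in raw data cannot produce impossible transitions; genuinely
impossible observed pairs (e.g. leaving the absorbing state) raise an error
naming the participant.

### Optimisation and numerics

`fit_intensities()` maximises the likelihood over unconstrained
log-intensities with BFGS (the same `vmmin` routine behind R's `optim`),
using an analytic gradient: with \(G_{ij} = N_{ij}/P_{ij}(\Delta t)\), the
gradient with respect to \(Q\Delta t\) is the adjoint Fréchet derivative of
the matrix exponential, computed exactly as the upper-right block of
\(\exp\!\big(\begin{smallmatrix} M^\top & G \\ 0 & M^\top
\end{smallmatrix}\big)\) — one 18×18 exponential per distinct interval
length, which keeps a full fit at a few milliseconds and makes the
500-replicate bootstrap calibration study below practical on one CPU. The
matrix exponential itself is Armadillo's scaling-and-squaring Padé
implementation; tests verify it against `Matrix::expm` to 1e-10 and against
closed forms. Default settings: three seeded starts (crude
events/person-time initial rates, then log-scale perturbations with SD 0.7)
to guard against local optima; relative log-likelihood tolerance 1e-8;
rates below 1e-6/year are flagged as boundary solutions. Standard errors
come from the observed information on the log scale, delta-method
transformed; absorption-time uncertainty uses the bootstrap instead.

Expected first-passage times to state 9 solve \((-Q_{TT})\tau = \mathbf 1\)
on the transient states that can reach it; unreachable states report
`Inf` rather than failing.

### Comparing progression speed by onset disease

The survey literature rarely states which test lies behind "progression
times differed"; we chose a parametric bootstrap and label it as such.
`compare_absorption_times()` re-simulates panels under the fitted \(\hat Q\)
on the *observed design* (same initial states, same observation grids),
refits each, and recomputes \(\tau\) from each start state. The global test
is a Wald chi-square on contrasts of \(\log\tau\) with the bootstrap
covariance (logs stabilise the right-skewed, strictly positive times);
pairwise contrasts use bootstrap standard errors of the log differences
with Bonferroni adjustment. Under an equal-speed generator this test
rejects at the nominal 5% level (the validation suite measures 2–8% over
500 scaled-down replicates with n = 500 participants and 200 bootstrap
draws each). Replicated refits start from \(\hat Q\) with a single start:
the refit surface is a perturbation of the original optimum, and
multi-start there would triple the cost without changing the answer.

## Pattern mining

`mine_frequent_itemsets()` is a levelwise Apriori with the anti-monotone
prune; its output is property-tested to be identical to exhaustive
enumeration over all itemsets. Defaults follow the survey analysis
conventions: minimum support 0.005, minimum rule confidence 0.07, age
bands 19–37/38–56/57–75/76–94 (ages outside the bands are excluded from
age-stratified mining only), and gender strata. Published pattern tables of
this kind print one percentage per combination with an unstated
denominator; we report the *within-order share* — among participants with
exactly k diseases, the fraction whose disease set equals the pattern —
because it reproduces the observable ranking behaviour of such tables
(singleton shares then agree with the one-disease column of the
descriptive table) while raw support is emitted alongside. Each pattern of
order ≥ 2 carries one lift: the maximum rule lift over its bipartitions.
Ties break by support, then lift, then lexically, so output is
deterministic. `select_trio()` picks the highest-support frequent
3-itemset under these tie rules.

## The synthetic cohort

The generator plays the role of the restricted survey data and defines the
study conditions: 11 biennial waves (20 years of follow-up), a longitudinal
cohort of 16,114 participants and a cross-sectional sample of 22,355 by
default, entry age N(60.2, 10.0), 45% female, everyone obese at entry
(BMI 30 plus a Gamma(2, 1.5) excess).

*Panel.* Trajectories are simulated in continuous time by competing
exponential clocks on the allowed edges (Gillespie-style) and observed only
at wave times — exactly the interval censoring the estimator must handle; a
per-wave multinomial mode using \(e^{Q\Delta t}\) is kept as a cross-check.
The default ground-truth \(Q\) is calibrated qualitatively to the dynamics
the model should exhibit — about 40% of healthy obese adults acquire a
chronic disease within 5 years, progression is faster from state 2 than
from state 1, and the metabolic-onset path to the trio is clearly the
fastest (expected times ≈ 9.0 years from MTD vs ≈ 12.2 from CVD and ≈ 13.4
from SMD under the defaults) — while every value remains configuration, not
constant. The initial-state distribution (33% healthy, 20% non-trio, 47%
spread over trio states) mirrors a cohort in which roughly a third is
disease-free at entry. Attrition exists in real panels but is not part of
the modelled story; a per-wave dropout probability is exposed and defaults
to 0.

*Cross-section.* Items are drawn from a latent-class mixture: with a solved
mixing probability an entire planted itemset is present; otherwise items
are independent with base rates adjusted so the configured marginals hold
exactly. The default plants {CVD, MTD, SMD} at lift 12 — the order of
magnitude such trios show in published co-occurrence tables — over
moderate marginals (CVD 0.30, MTD 0.18, SMD 0.22, …) chosen to keep that
lift feasible (a lift-12 trio is arithmetically impossible over very common
items, since the implied joint probability would exceed a marginal; the
generator refuses infeasible configurations). Planted itemsets must be
disjoint, which keeps the marginal adjustment exact and closed-form.

*Burden.* Each participant's true onset (first trio component acquired,
known from the simulated trajectory) selects the distribution of four
burden outcomes; defaults plant skeletal-muscular onset as the worst
profile — depression 6.3%, adverse (fair/poor) sleep 77%, work limitation
74% — with metabolic onset highest for poor self-rated health, so the
downstream chi-square comparisons have a known answer.

What passing tests on this cohort do **not** show: robustness to
informative attrition, to age-dependent intensities (the model is
age-homogeneous by design), to misreported diagnoses, or to real surveys'
variable wave spacing. The generator emulates the censoring structure and
planted effect sizes, not demographic realism.

## Burden analysis choices

Onset assignment from observed states is conservative: a participant must
be seen trio-free before their first trio component, exactly one component
may appear at that wave, and everyone else is `ambiguous` (prevalent at
entry, or two components between consecutive waves) or `none`; only
CVD/MTD/SMD-onset groups enter the tests. Burden is assessed at the last
observed wave (configurable to the onset wave). The 5-level ordinals are
collapsed to adverse = {fair, poor} — the cut that makes "77% poor sleep"
magnitudes reproducible — and the cut is configurable because published
analyses rarely state it. Categorical measures use Pearson chi-square
without continuity correction (determinism across implementations;
expected cells below 1 are flagged), continuous measures one-way ANOVA.

## Problem sizes used in the validation suite

The validation suite runs the miner-vs-enumeration equivalence on 100
random transaction sets (≤ 500 transactions), lift calibration at
n = 20,000, trio recovery over 100 seeded cross-sections, parameter
recovery at n = 2,000 participants × 10 biennial intervals (every intensity
with ≥ 50 observed interval pairs within ±20%, absorption times within
±15%), the null-calibration study at 500 replicates of n = 500 with 200
bootstrap draws, and one full-size default end-to-end run. These sizes were
chosen so the whole suite completes in minutes on a single core while
keeping every check at the scale its error bounds assume.

## Known limitations

- Intensities are age- and sex-homogeneous; covariate effects,
  time-inhomogeneity and hidden-state misclassification are out of scope.
- Death and dropout are not competing risks; the absorbing state is the
  triple comorbidity, not mortality.
- The bootstrap comparison assumes the fitted model generates the data
  (parametric bootstrap); it is not robust to gross model misspecification.
- Mining is plain Apriori over seven items; closed/maximal itemsets and
  rule significance testing are deliberately absent.
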