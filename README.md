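# morbiditrail

Chronic diseases rarely arrive alone in obese adults: cardiovascular (CVD),
metabolic (MTD) and skeletal-muscular (SMD) conditions cluster, and people
progress from health through single- and dual-disease states toward the
triple comorbidity. `morbiditrail` is an R package for quantifying that
progression from longitudinal health-survey panels. It is aimed at
epidemiologists and biostatisticians who have long-format wave data (one
row per participant per wave, seven binary disease-system indicators,
BMI, and simple health-burden measures) and want both the cross-sectional
co-occurrence structure and the longitudinal transition dynamics.

## What it computes

**Pattern mining.** A levelwise Apriori miner over the seven disease
systems (support/confidence/lift; defaults support ≥ 0.005, confidence
≥ 0.07), gender- and age-stratified ranked pattern tables, and automatic
selection of the modelling trio — the highest-support frequent 3-itemset.

**Nine-state progression model.** States: 1 healthy, 2 non-trio disease,
3–5 single trio diseases, 6–8 dual combinations, 9 triple comorbidity
(absorbing). Transitions follow single-acquisition steps on a DAG (16
edges). With states observed only at survey waves, the model is a
continuous-time Markov chain fitted by maximising the interval-censored
panel likelihood

    L(Q) = prod over consecutive observations [exp(Q * dt)]_{s0, s1}

over per-edge log-intensities (BFGS with exact matrix-exponential adjoint
gradients, implemented in C++). From the fitted generator `Q` the package
reports transition-probability matrices `P(t) = expm(Qt)` at 5/10/20-year
horizons, expected first-passage times to the absorbing state (solving
`(-Q_TT) tau = 1`), and a parametric-bootstrap comparison of progression
times by onset disease (global Wald test on log expected times plus
Bonferroni-adjusted pairwise contrasts).

**Burden analysis.** Onset identification (first trio disease observed
after a trio-free wave), prevalence tables of depression, work limitation,
poor sleep and poor self-rated health by onset type, with chi-square /
ANOVA tests.

**Synthetic cohort.** Because the motivating survey data are
access-restricted, a simulator generates ELSA-like cohorts with known
ground truth: biennial waves, Gillespie-simulated trajectories under a
known intensity matrix observed with interval censoring, planted
cross-sectional co-occurrence (default: {CVD, MTD, SMD} at lift 12) and
onset-conditional burden outcomes. Every stage of the pipeline is tested
against this truth or against closed-form oracles.

## Worked example

```r
library(morbiditrail)

cfg <- synthetic_config(seed = 7, n_participants = 2000,
                        n_cross_section = 8000)
run <- run_pipeline(cfg, n_boot = 200, quiet = TRUE)
print(run)
```

```
# Comorbidity trajectory report

- Independent sample: 1978 participants; longitudinal sample: 1978 participants, 21758 person-observations.
- Selected trio: CVD-MTD-SMD.
- Log-likelihood at the optimum: -10198.98 (converged).

## Expected years to triple comorbidity

- MTD: 9.61 years (95% CI 8.98-10.22)
- CVD: 12.44 years (95% CI 11.84-13.15)
- SMD: 14.11 years (95% CI 13.35-15.15)
- Fastest onset path: MTD.
- Global equality test: chi-square = 99.63, df = 2, p = 2.32e-22.

## Health burden by onset

- depression: highest in SMD onset (7.8%).
- work limitation: highest in SMD onset (75.1%).
- poor or fair sleep quality: highest in SMD onset (74.6%).
- poor or fair self-rated health: highest in MTD onset (59.6%).
```

Reading this: the miner recovered the planted {CVD, MTD, SMD} trio; the
fitted intensity matrix implies metabolic-first progression to the triple
comorbidity is about 3 years faster than cardiovascular-first and about
4.5 years faster than skeletal-muscular-first (the ground truth the cohort
was simulated under: 9.0 vs 12.2 vs 13.4 years); the global test correctly
rejects equal progression speeds; and the planted burden gradient
(skeletal-muscular onset worst for depression, sleep and work limitation)
is reproduced. `run$fit` prints per-edge intensities with standard errors
and observed transition counts, and `run$transition_matrices$P5` etc. hold
the horizon matrices. Use `run_pipeline(cfg, out_dir = "runs/demo")` to
write every stage output (summaries, rule tables, intensity and
probability matrices, burden table, manifest, report) to disk.

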