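---
title: "Methods: standardised-rate variation and STAR value-for-money analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardised-rate variation and STAR value-for-money analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starvalue)
```

`starvalue` supports a population approach to value improvement in
back-pain care: quantify unwarranted variation in elective hospital
activity between general practices, examine equity across deprivation
groups, and evaluate budget-neutral reallocation of a fixed spend from
low-value to high-value interventions in QALY terms. This vignette
documents the statistical models, the synthetic-data generator, the
numerical choices, and what the test suite does and does not
demonstrate.

## Direct age-sex standardisation

Practices and deprivation groups differ in age-sex structure, so crude
rates are not comparable. We use direct standardisation to the 2013
European Standard Population (ESP): for strata $s$ (five-year age band
$\times$ sex) with events $e_s$, person-years $d_s$ and ESP weight
$w_s$,

$$\mathrm{DSR} = 10{,}000 \times \frac{\sum_s w_s\, e_s / d_s}{\sum_s w_s}.$$

Weights are normalised internally, so any uniform rescaling of the
standard population leaves the rate unchanged, and identical weights
are applied to both sexes (the ESP does not differentiate by sex).

Choices worth recording:

- **ESP version.** The 2013 revision (19 five-year bands totalling
  100,000; we merge the <1 and 1–4 rows into 0–4). An analysis period
  of 2015–2020 post-dates the 2013 revision, making it the natural
  default; `esp_weights()` output can be replaced by any
  `(age_band, weight)` table.
- **Adults-only banding.** Analyses are restricted to ages 18+. Ages
  18–19 are assigned to the 15–19 ESP band, which keeps its full
  weight. This is the simplest defensible alignment; the band set is
  configurable via `sim_config()`.
- **Empty strata.** A stratum with events but zero person-years is a
  data-integrity error (it names the stratum). A stratum with neither
  events nor person-years is skipped with a message: erroring would
  block legitimately sparse registers, and silent imputation would
  fabricate information.
- **Scale.** Rates are reported per 10,000 population; full precision
  is retained internally and never rounded before output.

### Confidence intervals

Two interval methods are used, recorded in the output `ci_method`
field:

- **Crude proportions:** the Wilson score interval on $e/d$, rescaled
  to per-10,000. Its coverage is pinned by a Monte-Carlo test (2,000
  binomial draws at $p = 0.01$, $n = 5{,}000$; observed coverage must
  lie in 93–97% for a nominal 95% interval).
- **Standardised rates:** the Dobson method — exact gamma limits
  $(X_L, X_U)$ for the total event count $X$, transferred to the
  standardised scale by
  $\mathrm{DSR} + \sqrt{\widehat{\mathrm{var}}(\mathrm{DSR})/X}\,(X_{L,U} - X)$
  with $\widehat{\mathrm{var}}(\mathrm{DSR}) =
  \sum_s w_s^2 e_s/d_s^2 / (\sum_s w_s)^2$. With zero events the lower
  limit is 0 and the upper limit is the exact Poisson bound on the
  total count spread over the total person-years.

Both are standard public-health practice. Whether published analyses
of this kind compute intervals on crude counts or on the standardised
scale is often unstated; the package provides both, and each rate row
records which was used. Multi-year pooling sums events over the
selected years and multiplies register person-years by the number of
years (registers are held constant per year unless per-year registers
are supplied); pooling identical years leaves the point rate unchanged
and shrinks interval width like $1/\sqrt{n}$, which the tests verify
within 10%.

## The synthetic-data generator

No patient-level hospital extract can be shipped, so the generator
emulates one with the statistical structure the analyses assume.
Stratum event counts are Poisson:

$$E_{p,b,x,d,y} \sim \mathrm{Poisson}\!\big(\lambda_0\, m(b,x)\,
e^{u_p}\, g(d)\, N_{p,b,x,d}\big),$$

with $\lambda_0$ the base rate per person-year (`base_rate`),
$m(b,x)$ an age-band–sex multiplier, $u_p \sim N(0,
\sigma^2_{\mathrm{practice}})$ a log-scale practice effect, and
$g(d) = r^{(10-d)/9}$ a log-linear deprivation multiplier so that
decile 1 (most deprived) versus decile 10 equals the configured rate
ratio $r$. A Poisson count model is the natural choice for rare
episode counts; overdispersion beyond the practice effect is not
modelled.

Defaults represent the study conditions the package is designed
around: 40 general practices, four fiscal years (2016/17–2019/20),
adults 18+, `practice_sigma = 0.45` (which yields the three-to-eight-fold
practice variation regime), `decile_rate_ratio = 2` (a weak-to-moderate
gradient with higher rates in more deprived deciles), and
`age_shift_years = 2`. Stratum-level rates are not published for this
setting, so `base_rate = 0.01` per person-year at the reference
stratum and the unimodal age profile peaking in the early 60s (with a
mild female excess) are plausibility choices, stated once here and not
tuned thereafter. Register sizes default to 4,000–9,000 adults per
practice.

Design decisions:

- **Practice deprivation is a deliberately noisy proxy.** Each
  practice draws a decile mixture (a discretised Gaussian around a
  practice-specific centre; the centre range extends past the decile
  ends so the marginal decile distribution is roughly uniform, as
  population deciles are). The practice `deprivation_score` is the
  register-weighted mean decile IMD score, so practices mix markedly
  different neighbourhoods and the practice-level score is a poor
  marker of individual patients' deprivation — which is exactly the
  property the variation analysis probes.
- **Age-at-procedure shift.** In decile $d$ the procedure rate at age
  $a$ equals the least-deprived rate at age
  $a + s\,(10-d)$ with $s$ = `age_shift_years`; deprivation moves the
  whole incidence profile towards younger ages. Because the register
  age structure stays fixed, the realised mean age-at-procedure gap
  between decile 1 and decile 10 is smaller than the nominal
  $9s = 18$-year profile shift — about 11–12 years at the defaults —
  while the modal decades show the 40s (most deprived) versus 60s
  (least deprived) pattern, a two-decade modal gap. Attendance rates
  use the unshifted profile, so the realised procedure share equals
  `procedure_fraction` exactly only when the shift is zero.
- **Seeding.** One seed governs everything through named substreams
  (registers, episodes), so adding a generator never perturbs another
  generator's draws, and identical configurations are byte-identical.
- **Patients.** Single-episode by default; `repeat_episode_rate`
  reassigns a fraction of episodes to existing patients with the same
  practice, sex and decile, since people with back pain may receive
  more than one intervention. No within-year seasonality; fiscal years
  are opaque labels.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: clinical coding (interventions are opaque
identifiers; no OPCS/ICD-10/HRG logic), emergency and trauma activity,
migration between practices, secular trends within or across years,
overdispersion beyond the practice effect, and any correlation between
deprivation and register age structure. Parameter-recovery tests
demonstrate that the *pipeline* estimates what was injected, not that
the defaults match any particular health economy.

## Variation and equity analyses

`practice_rates()` computes one standardised rate per practice (sorted
descending, the bar-chart order) and `fold_variation()` reports the
ratio of the highest to the lowest *positive* rate. Zero-rate
practices are excluded from the denominator and listed explicitly:
division by zero is meaningless and silently imputing a floor would
fabricate variation. With a single unit the fold is reported as 1 with
a flag. The deprivation correlation defaults to Spearman rank — the
question is whether deprivation *orders* the rates, and a rank method
avoids asserting linearity — and no p-value is attached by default.
No shrinkage or funnel-plot adjustment is applied to small practices;
raw standardised rates with intervals are reported.

`decile_rates()` standardises procedure rates by IMD decile of patient
residence (decile 1 = most deprived throughout, the standard IMD
convention). `first_procedure_per_patient()` takes the earliest
procedure in the loaded window — no look-back rule beyond the supplied
data, with ties within the earliest year broken deterministically by
record order and the tie count attached. The age-deprivation matrix
column-normalises first procedures over decade bands (18–29, 30s, …,
80+; "people in their 40s" is the natural resolution for this
analysis) per deprivation group, at decile or quintile grouping; empty
groups are flagged, not errored. No trend test is run by default: with
ten ordered groups and visible gradients, a test would add false
precision to what is a descriptive equity display.

## STAR value-for-money

Each intervention's value triangle has total QALY gain
$Q_i = n_i q_i$ against total cost $C_i = F_i + n_i v_i$, and value
for money is the slope $Q_i/C_i$. The efficiency frontier stacks
triangles in slope order, steepest first; the cumulative
(cost, QALY) curve is then piecewise-linear and concave, and a
brute-force test verifies that for up to six triangles the
slope-ordered curve weakly dominates every other stacking order at
every cost breakpoint. Ties are broken by lower total cost, then id —
deterministic output. Interventions with zero or negative QALY gain
are placed last, in evidence-category order (no evidence, no benefit,
possible harm).

Numerical note: costs and QALYs are decimal quantities (pounds;
QALYs-per-person to a few decimal places), and products like
$3{,}000 \times 0.67$ are not exactly representable in binary floating
point. Triangle totals and cumulative sums are therefore snapped to
six decimal places so the triangle identities hold exactly at the
scales used. Cost per QALY is rounded to the nearest pound for
display; totals are never rounded internally.

### Reallocation

A plan lists disinvestments — a fraction of an intervention stopped
and the fraction of the freed cost that is actually *releasable*
(facility-type fixed costs often are not) — and reinvestments. The
released budget is

$$B = \sum_j f_j\, \rho_j\, n_j v_j,$$

over disinvestments $j$ with stop fraction $f_j$ and releasable
fraction $\rho_j$: only the variable share of cost can be released,
which encodes the practical observation that many fixed costs cannot
be redirected. Scaled-down interventions keep their fixed cost, treat
$n_j(1-f_j)$ people and lose QALYs proportionally. Two budget modes:
`released_only` (reinvestment spend must not exceed $B$; total spend
falls by exactly the unreleased savings) and `fixed_envelope` (total
spend after the plan must equal the envelope within £1, asserting
budget neutrality). Infeasible plans error with the shortfall.

Evidence categories map to QALYs conservatively: interventions tagged
no-evidence, no-benefit or possible-harm carry zero QALYs unless an
explicit (possibly negative) value is supplied — so stopping them
loses nothing in the QALY total, which is what makes the headline
reallocation arithmetic (baseline QALYs + reinvestment QALYs) exact.
`n_people` counts treatment courses (the sum of `n_treated`); a
person-level deduplicated count would require patient-linked data,
which the portfolio table does not carry.

The shipped `synthetic_baseline_portfolio()` is a synthetic 29-row
portfolio constructed to the published study-level *inputs* — 17,225
treatment courses, £4.5M, 4,571 QALYs, evidence tally 16/9/3/1 — with
invented intervention-level rows; the accompanying plan releases
exactly £270,000 and reinvests it in the three worked-example
interventions (10,000 people at £2 and 0.07 QALYs; 3,000 at £50 and
0.67; 200 at £500 and 1.90), yielding 7,661 QALYs inside the same
envelope.

## Problem sizes and test design

The test suite generates all data programmatically. The heavier
checks use these sizes, chosen to give adequate Monte-Carlo power at
desk-scale runtimes:

- Deprivation-gradient recovery: 40 practices × 30,000 adults × 2
  years (≥ 10⁵ person-years per decile, comfortably), recovered ratio
  within ±10% of the injected 2.0.
- Null practice variation (σ = 0): 40 practices × 8,000 adults × 2
  years; practice intervals must be pairwise CI-overlapping
  (consistent with one common rate).
- Fold-variation regime (σ = 0.45): 200 replicates of 40 practices ×
  2,000 adults × 1 year; the median fold must exceed 3. Small
  registers add Poisson noise on top of the log-normal spread, so the
  observed median sits well above 3 — matching the qualitative point
  that observed small-sample variation overstates underlying
  variation.
- Age-shift pattern: 30 practices × 10,000 adults × 3 years,
  procedures only; modal decades 40s vs 60s and a mean gap in the
  10–20-year band.
- Interval coverage: 2,000 binomial draws; frontier dominance: 100
  random instances of up to 6 triangles against all permutations.

## Known limitations

- The generator's Poisson model has no overdispersion beyond the
  practice effect, no patient frailty, and no correlation between a
  practice's deprivation mix and its age structure.
- QALY-per-person values are inputs; the package performs no QALY
  estimation, discounting, or uncertainty propagation on them.
  Sensitivity to those inputs should be explored by rerunning plans
  with varied values.
- Indirect standardisation (SMRs) is not provided; analyses are
  direct-standardisation only.
- The deprivation correlation is descriptive; no inference is
  attached, by design.
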