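# starvalue

Population value-improvement analysis for elective back-pain care.

Commissioners and clinical networks that steward a fixed budget for a
whole condition — here, back pain across a group of general practices —
face two linked questions: *is the care we provide distributed fairly*
(or does hospital activity vary between practices and deprivation
groups in ways clinical need cannot explain), and *is the portfolio of
interventions we pay for buying as much health as it could*? `starvalue`
implements the quantitative core of that analysis as a reusable, tested
R pipeline:

- **Synthetic hospital-episode data.** Patient-level elective episodes
  and practice registers with configurable between-practice rate
  dispersion (log-normal practice effects), a log-linear deprivation
  rate gradient across IMD deciles, and a deprivation-dependent shift
  of procedures towards younger ages — so every downstream analysis is
  testable without access to restricted administrative data.
- **Direct age-sex standardisation.** Rates per 10,000 standardised to
  the 2013 European Standard Population, with 95% confidence intervals
  (Wilson score for crude proportions; Dobson-style gamma intervals for
  standardised rates) and multi-year pooling.
- **Practice variation.** Fold-variation (highest / lowest positive
  standardised rate, zero-rate practices excluded and listed) and the
  Spearman correlation of practice rates with practice deprivation.
- **Deprivation equity.** Standardised procedure rates by IMD decile of
  patient residence, first-procedure extraction per patient, and the
  age-decade x deprivation percentage matrix with modal age bands.
- **STAR value-for-money.** For each intervention a value triangle:
  QALY gain `Q = n x q` (people treated x mean QALY gain per person)
  against cost `C = F + n x v` (fixed plus variable), with value for
  money as the slope `Q/C`. Triangles stack into an efficiency frontier
  in slope order (steepest first), and budget-neutral reallocation
  plans — stop or scale down low-value interventions, release the
  releasable share of their variable cost, reinvest in higher-value
  ones — are evaluated in QALYs under a fixed spend envelope.

## Worked example

The package ships a synthetic 29-intervention baseline portfolio
(constructed to the study-level input totals: 17,225 treatment courses,
£4.5M spend, 4,571 QALYs, evidence tally 16/9/3/1) and a reallocation
plan that stops the zero-benefit imaging and injection lines and
reinvests the released £270,000 in three new interventions.

```r
library(starvalue)

reinvest <- generate_portfolio(sim_config(seed = 1))
cost_per_qaly(reinvest)
#> [1]  29  75 263

build_frontier(value_triangle(reinvest))
#> # A tibble: 3 x 7
#>    rank intervention_id    slope total_cost total_qaly cumulative_cost cumulative_qaly
#>   <int> <chr>              <dbl>      <dbl>      <dbl>           <dbl>           <dbl>
#> 1     1 digital_support   0.035       20000        700           20000             700
#> 2     2 back_pain_classes 0.0134     150000       2010          170000            2710
#> 3     3 case_management   0.0038     100000        380          270000            3090

apply_reallocation(synthetic_baseline_portfolio(),
                   synthetic_reallocation_plan())
#> <reallocation_result>
#>   released £270,000 | reinvested £270,000 (fixed_envelope mode)
#>   QALYs: 4,571 -> 7,661 (+67.6%) | people: 17,225 -> 26,975 | spend change £0
```

Reading the numbers: the three reinvestments cost £29, £75 and £263 per
QALY; together they buy 3,090 QALYs for £270,000. Redirecting exactly
the released spend keeps the £4.5M envelope intact while total QALYs
rise from 4,571 to 7,661 (+67.6%) and 9,750 more treatment courses are
provided.

A full synthetic run — simulate, standardise, variation, equity, STAR —
with CSV outputs, a combined JSON report and a checksummed manifest:

```r
cfg <- sim_config(seed = 1, portfolio_spec = synthetic_baseline_portfolio())
run_pipeline(cfg, "out", plan = synthetic_reallocation_plan())
# or from a shell:
#   Rscript scripts/pipeline.R --config cfg.yaml --out out
```

## Vignette

`vignettes/value-variation-methods.Rmd` documents the statistical
methods, the generator's design and its limitations, the numerical
choices (ESP version, interval methods, tie-breaking, zero handling),
and the problem sizes used in the test suite.
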