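# workergf

Parametric g-formula estimation of the mortality impact of occupational
exposure in cohorts subject to **healthy worker survivor bias**.

## The problem

In occupational cohorts, healthier workers stay employed longer and so
accrue more exposure, while leaving work predicts both death and all future
exposure (no one accrues workplace exposure after leaving). Employment
status is therefore a time-varying confounder *affected by prior exposure*:
adjusting for it in a regression either removes the part of the exposure
effect mediated by staying at work or induces collider bias, yet ignoring it
confounds the estimate. The g-formula resolves this by *standardizing* over
the confounder history instead of conditioning on it. Its parametric Monte
Carlo version fits discrete-time models for each process and simulates the
cohort forward under hypothetical workplace interventions.

`workergf` implements the full pipeline for an annual, age-scale cohort with
three competing causes of death (respiratory cancer, heart disease, other),
employment entry/exit dynamics, and an ordinal exposure-intensity process
(light / medium / heavy work areas, airborne concentrations 0.29 / 0.58 /
11.4 mg/m^3) active only while employed. Cumulative exposure is the
concentration-weighted metric

    d = 0.29 y_L + 0.58 y_M + gamma * 11.4 y_H   (mg/m^3-years, gamma = 0.1),

entering the hazard models lagged 2 years in windows (2,5], (5,10] and
(10,20] years since accrual. Six models are fit by Newton-type maximum
likelihood — pooled logistic hazards for the three causes of death and for
leaving/returning to work, and a proportional-odds model for exposure
category — then a Monte Carlo engine simulates pseudo-cohorts under five
interventions (`natural_course`, `never_exposed`, `always_light`,
`always_medium`, `always_heavy`). Cause-specific cumulative incidence uses
a discrete Aalen–Johansen estimator with late entry; contrasts are reported
as deaths and excess deaths per 1,000 at ages 60 and 70 with worker-level
percentile bootstrap confidence intervals.

Because no such cohort is public, the package ships a **synthetic cohort
generator** with a known data-generating process (including the
exposure → leaving-work loop that creates survivor bias, coefficient 2.3
log-odds per mg/m^3-year of recent exposure) whose generating coefficients
are keyed exactly like the fitted ones — so every claim the package makes is
testable against ground truth.

## Worked example

```r
library(workergf)

co <- generate_cohort(generator_params(n_workers = 2000, seed = 101))
co
#> Synthetic occupational cohort: 2000 workers, 67665 worker-years
#>   vital status: alive 38.4%, resp_cancer 5.3%, heart 20.8%, other 35.5%

cfg <- pipeline_config(interventions = c("natural_course", "never_exposed",
                                         "always_heavy"),
                       mc_size = 10000, seed = 7)
res <- run_analysis(co$baseline, co$history, cfg)
res$suite
#> g-formula model suite:
#>   d_resp             binary_logit, 15 coef, AIC 1440.9
#>   d_heart            binary_logit, 15 coef, AIC 4576.0
#>   d_other            binary_logit, 15 coef, AIC 7045.8
#>   leave_work         binary_logit, 6 coef, AIC 15033.4
#>   return_work        binary_logit, 5 coef, AIC 21675.7
#>   exposure_category  proportional_odds, 3 coef, AIC 40914.4

print(res$contrasts, digits = 3)
#>      age       cause deaths_per_1000_reference excess_natural_course excess_always_heavy
#> 1:    60         all                     159.5                 48.78               50.72
#> 2:    60 resp_cancer                      11.8                  2.31                2.22
#> 3:    60       heart                      62.1                  8.55               10.67
#> 4:    60       other                      85.6                 37.93               37.83
#> 5:    70         all                     341.1                 91.12              109.66
#> 6:    70 resp_cancer                      26.0                  5.97                7.41
#> 7:    70       heart                     132.7                 12.31               17.11
#> 8:    70       other                     182.4                 72.84               85.14
```

Reading the table: under the no-exposure intervention, 341 of 1,000 workers
would have died of any cause by age 70; letting exposure follow its natural
course adds an estimated 91 deaths per 1,000 by that age (6 respiratory
cancer, 12 heart disease, 73 other); forcing heavy exposure while at work
adds 110. The natural-course run doubles as a model diagnostic -- its
simulated incidence should track the observed data:

```r
res$calibration
#> Natural-course calibration (through age 70)
#>   max |observed - simulated| cumulative incidence:
#> cif_resp_cancer       cif_heart       cif_other         cif_all
#>          0.0048          0.0062          0.0079          0.0142
#>   cumulative exposure quantiles (mg/m^3-years, all person-time):
#>            25%  50%  75%
#> observed  2.59 3.77 5.74
#> simulated 2.57 3.75 5.74
```

Percentile bootstrap intervals (resampling workers, refitting all six
models, re-simulating every intervention per replicate):

```r
cfg$bootstrap <- TRUE   # B = 200 by default; 1500 for a full run
bt <- bootstrap_cis(co$baseline, co$history, cfg)
```

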