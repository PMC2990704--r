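# crcscreen

Decision-analytic cost-effectiveness model of colorectal cancer (CRC)
screening for average-risk adults aged 50–75, in R.

Population screening for CRC can be done with very different tools — guaiac
fecal occult-blood tests (FOBT), fecal immunochemical tests (FIT), fecal DNA
assays, flexible sigmoidoscopy, CT colonography (CTC), or colonoscopy — that
differ in sensitivity for adenomas and cancer, specificity, screening
interval, adherence, complication risk, and cost. `crcscreen` lets a health
economist compare these strategies, and a no-screening natural-history arm,
on lifetime costs (2008 CAN$) and quality-adjusted life-years (QALYs).

## The model

Disease follows the adenoma–carcinoma sequence with a one-year cycle:

```
normal colon → nonadvanced adenoma → advanced adenoma → CRC (undiagnosed)
                                                          → CRC (diagnosed) → death
```

Each year a person can die of background causes (age-stratified annual risk),
die of CRC within five years of diagnosis (a constant annual hazard *h* per
stage, with 1 − (1 − *h*)⁵ equal to the stage's five-year mortality), be
screened, progress, or present symptomatically (annual probability *q*).
Stage at diagnosis (I–IV) is drawn from a detection-context distribution:
symptomatic cancers carry the least favourable stage mix, stool-detected
cancers an intermediate one, and structurally detected cancers
(colonoscopy/CTC/flexible sigmoidoscopy) the most favourable. Costs accrue
per screening event, complication, and as a stage-based lump sum at
diagnosis; utilities are 0.91 (no diagnosed CRC), 0.74 (stage I–II, first
five years), 0.46 (stage III–IV, first five years). Costs and QALYs are
discounted at 5%/year.

Screening includes imperfect adherence (68% first offer, 63% subsequent,
81% follow-up colonoscopy after a positive test), polypectomy with
therapeutic-colonoscopy complication risks, 3/5-year surveillance
colonoscopy after findings, and a ten-year exemption after a clean
colonoscopy. Strategy comparison uses incremental cost-effectiveness
ratios (ICER = ΔC/ΔE) after eliminating strongly and extendedly dominated
strategies; parameter uncertainty is handled by second-order probabilistic
sensitivity analysis (beta/triangular/log-normal distributions over every
ranged input).

Two engines share one model structure: a vectorised first-order Monte Carlo
microsimulation (`run_microsim()`) for count outcomes, and a deterministic
cohort-expectation engine (`run_cohort_expectation()`) that propagates the
full joint state distribution — including every screening-cascade branch —
by probability mass, for noise-free cost/QALY and calibration work. Their
agreement within Monte Carlo error is enforced by the test suite.

## Worked example

Calibrate the natural history so the no-screening arm reproduces reference
lifetime outcomes (4,857 CRC diagnoses and 1,782 CRC deaths per 100,000),
then simulate annual FIT with mid-range test performance:

```r
library(crcscreen)

cal <- calibrate_natural_history()
glance(cal)
#> # A tibble: 1 × 4
#>   converged objective cancers_per_100k deaths_per_100k
#>   <lgl>         <dbl>            <dbl>           <dbl>
#> 1 FALSE      0.000914            4977.           1751.

params <- cal$params
run_microsim(strategy("FIT-mid"), params, n_persons = 100000, seed = 1)
#> <outcome_tally> FIT-mid (n = 100,000, seed 1)
#>   cancers                       1,382 per 100,000
#>   crc_deaths                      424 per 100,000
#>   primary_tests             1,141,854 per 100,000
#>   colonoscopies                89,066 per 100,000
#>   mean discounted cost   CAN$1446.64
#>   mean discounted QALYs  15.1065
```

Calibration lands within 2.5% of the incidence target and 1.7% of the
mortality target (the `converged` flag applies a strict 2% criterion; see
the methods vignette for why this is the structural optimum). Relative to
the calibrated no-screening arm (4,977 cancers, 1,751 deaths per 100,000),
annual FIT-mid screening prevents about 72% of cancers and 76% of CRC
deaths at the price of roughly 11.4 stool tests and 0.9 colonoscopies per
person.

Incremental analysis across the core comparators:

```r
res <- simulate_strategies(params, core_scenario_strategies())
incremental_analysis(res)
#> <cea_result>
#>        label    cost    qaly    status      icer
#>         none 1172.07 15.0619  frontier        NA
#>      FIT-mid 1472.02 15.1104  frontier   6174.54
#>     FIT-high 1628.89 15.1119  frontier 105473.53
#>  colonoscopy 2113.10 15.1087 dominated        NA
```

Here annual FIT-mid buys its extra 0.049 QALYs per person at about
CAN$6,200 per QALY versus no screening, FIT-high adds a sliver of benefit
at a steep ICER, and ten-yearly colonoscopy is dominated. `tidy()` /
`glance()` return these tables as tibbles; `autoplot()` draws the
cost-effectiveness plane and the PSA scatter. Sensitivity scenarios
(biennial FIT, differential adherence, administrative costs, chemotherapy
without biologics, excluding nonmedical costs, …) run through
`scenario_run()`; see `scenario_definitions()`.

A thin command-line wrapper over these functions ships in
`inst/cli/crcscreen.R` (subcommands `params`, `simulate`, `cea`,
`scenario`, `report`).

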