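---
title: "Methods: the crcscreen natural-history and cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the crcscreen natural-history and cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

`crcscreen` is a state-transition model of colorectal cancer (CRC)
screening in average-risk adults. This vignette documents the model
structure, its parameters and their defaults, the two simulation engines,
the calibration procedure, the economic accounting rules, the design
choices made where the problem was genuinely open, and the model's known
limitations. Nothing here reports an empirical result that the package's
tests or `scripts/acceptance.R` do not themselves compute.

## Disease model

All cancers arise through the adenoma–carcinoma sequence

> normal colon → nonadvanced adenoma → advanced adenoma → CRC,

with a one-year cycle. A person occupies a single worst-lesion state; no
multi-polyp bookkeeping is attempted, and the post-polypectomy condition is
the lesion-free state with a history flag that selects the higher adenoma
recurrence rate. Nonadvanced adenomas are tubular adenomas under 10 mm;
advanced adenomas are ≥10 mm or carry ≥25% villous histology or
high-grade dysplasia.

Within each cycle events take a fixed order:

1. background mortality (annual risk 0.005 below age 65, 0.018 from 65);
2. CRC-specific mortality for diagnosed patients in years 1–5 after
   diagnosis;
3. any screening or surveillance contact;
4. lesion progression (new adenoma 0.02/year, or 0.038/year with an
   adenoma/CRC history; nonadvanced → advanced 0.019/year; advanced → CRC
   0.048/year);
5. symptomatic presentation of undiagnosed CRC (0.4/year by default);
6. utility accrual for survivors, then the age increment.

Mortality precedes diagnosis within a cycle so a person cannot be
diagnosed and die of that diagnosis in the same year, which would
double-count the stage-specific hazard. The cycle order is shared verbatim
by both engines. Undiagnosed CRC carries background mortality only: stage
— and hence survival — is assigned at diagnosis, so an excess hazard
before diagnosis would have no stage to draw from. The symptomatic
presentation probability is therefore the model's only representation of
the preclinical sojourn, and it is deliberately exposed as a calibration
knob.

Stage at diagnosis (I–IV) is drawn from the distribution matching the
detection context — symptomatic/unscreened (0.145/0.356/0.280/0.219),
stool-test detected (0.305/0.318/0.243/0.134), or structurally detected
(0.425/0.226/0.267/0.082). Screen-detected cancers are thereby more often
early-stage, which is how screening improves survival in this model.
Five-year stage mortality (0.068/0.175/0.405/0.919) is converted to a
constant annual hazard `1 - (1 - m5)^(1/5)` applied for exactly five
years, after which survivors revert to background mortality ("cure"). The
same five-year window bounds the utility decrement.

The cohort enters at age 50 (with prevalent nonadvanced adenomas 17.1%,
advanced adenomas 3.8%, undiagnosed CRC 0.1%) and is followed to age 100.
The two printed age strata (50–64, 65–75) supply prevalence and background
mortality; ages above 75 reuse the 65–75 values. One cohort entering at 50
with a parameter switch at the 65th birthday is modelled; an alternative
reading — a second cohort entering at 65 — is supported simply by raising
`settings.screen_start_age` in a configuration file.

## Screening machinery

A strategy is a modality, an interval (annual FOBT/FIT, 3-yearly fecal
DNA, 5-yearly flexible sigmoidoscopy and CT colonography, 10-yearly
colonoscopy), and the 50–75 screening window. Screening **and**
surveillance both stop after age 75. Test performance is per person:
positivity is the class-specific sensitivity for the worst lesion present,
or one minus specificity in its absence.

The cascade: an offer is made whenever the interval has elapsed; adherence
is redrawn independently at every offer (0.68 first-ever, 0.63 after,
with per-strategy overrides for adherence scenarios — no persistent
never-screener class). A positive non-colonoscopy test leads to follow-up
colonoscopy with probability 0.81; colonoscopy-as-primary proceeds
directly. Design choices in the cascade, made where practice conventions
had to fill gaps:

* **Lesion removal only by colonoscopy.** Stool tests, CTC and flexible
  sigmoidoscopy only detect; the follow-up colonoscopy applies its own
  sensitivity row (the "after positive CTC" row for CTC referrals, which
  is higher because the target is known). Flexible sigmoidoscopy's
  sensitivity already includes lesions found at the ensuing colonoscopy,
  so no additional left/right-colon geometry is modelled.
* **Stage context at follow-up.** Cancers found at colonoscopy after a
  positive stool test use the stool-detected stage distribution (the stool
  test initiated detection); CTC and flexible-sigmoidoscopy referrals use
  the structural distribution.
* **Findings schedule surveillance**: 3 years after an advanced adenoma or
  resected cancer, 5 years after a nonadvanced adenoma. Surveillance
  colonoscopy adherence is 0.81 (the follow-up rate; a configurable
  setting). A missed surveillance appointment is re-offered the next year.
  Patients whose cancer presents symptomatically are managed outside the
  screening programme and do not re-enter it.
* **A clean colonoscopy restarts the clock**: any negative colonoscopy
  (primary, follow-up, or surveillance) exempts the person from screening
  for ten years (`settings.clean_colonoscopy_exempt_years`, configurable).
  This prevents double-counting protection from repeated examinations.
* **False positives.** A false-positive stool test leads to a diagnostic
  (not therapeutic) colonoscopy, since there is no polyp to remove. A
  false-positive CTC is read as a real but non-adenomatous polyp: the
  colonoscopy removes it (therapeutic cost and complication risks), and
  with probability 0.41 — the fraction of sub-centimetre polyps that are
  adenomatous — the histology triggers 5-year surveillance.
* **Complications.** Each colonoscopy draws bleeding then perforation at
  diagnostic (0.0003/0.0009) or therapeutic (0.005/0.0024) risks;
  perforation is fatal with probability 0.049. Flexible sigmoidoscopy
  itself perforates at 0.0002 with the same fatality; CT colonography
  perforation defaults to 0 and, when enabled, is costed but never fatal.

## Economic accounting

Costs are 2008 Canadian dollars, discounted at 5%/year from age 50 (year 0
undiscounted), from a public-payer perspective plus patient time-and-travel
(nonmedical) costs; productivity losses are excluded. Stool kits cost
their kit/processing fee (FOBT 12, FIT 19, fecal DNA 336) plus a 36
nonmedical cost per test; CTC 582 + 105; flexible sigmoidoscopy 650 + 105;
colonoscopy 857 (diagnostic) or 999 (therapeutic) plus 308; bleeding
3,194; perforation 31,223. An administrative cost per screening test
(default 0; 10–50 in scenarios) attaches to every primary test. CRC
management (25,049 / 36,143 / 96,768 / 134,014 for stages I–IV) is charged
once, in full, in the diagnosis year: the inputs are stage totals with no
published annual profile, and a lump sum at diagnosis keeps the discounted
comparison between early and late detection conservative.

QALYs weight each lived year by 0.91 (no diagnosed CRC, including
undiagnosed cancer and post-polypectomy), 0.74 (diagnosed stage I–II) or
0.46 (diagnosed stage III–IV) during the five years after diagnosis, and
0.91 thereafter. The early/advanced split at stage II/III mirrors the
mortality contrast; the utility study behind the weights is
stage-dependent but does not pin the mapping. There is no half-cycle
correction, and the year of death contributes no utility — death occurs at
the cycle start under the event ordering, so crediting the year would
contradict it.

## Two engines, one structure

`run_microsim()` simulates persons individually (vectorised across the
cohort) and is the source of count outcomes — cancers, deaths, tests,
colonoscopies, complications. Natural-history and screening random numbers
come from two separate streams derived from the master seed, so arms that
share a seed share disease trajectories: a zero-adherence strategy
reproduces the no-screening arm *exactly*, and paired between-strategy
contrasts carry no natural-history noise.

`run_cohort_expectation()` propagates the joint occupancy distribution
over (state, stage, years-since-diagnosis, history, surveillance clock,
exemption clock, offer clock, ever-offered flag) and treats every cascade
branch — adherence × result × follow-up × detection × stage × complication
— analytically by probability mass. It is deterministic and is used
wherever small differences matter: base-case cost/QALY tables,
calibration, and the PSA. The microsimulation's means converge to it as
the cohort grows; the test suite enforces agreement within three Monte
Carlo standard errors at n = 20,000 (and at n = 100,000 in the acceptance
checks), alongside exact probability-mass conservation every cycle.

## Calibration

Unobserved natural-history rates cannot be taken at face value: with the
default transitions the no-screening arm yields roughly 14,500 lifetime
CRC diagnoses per 100,000 — three times the reference target of 4,857
diagnoses (with 1,782 CRC deaths) that the no-screening arm should
reproduce. `calibrate_natural_history()` therefore searches the four
transition probabilities inside their plausible ranges (0.01–0.03,
0.03–0.05, 0.01–0.03, 0.03–0.07) and the symptomatic-presentation
probability inside 0.1–0.8 (a mean preclinical sojourn of 1.25–10 years,
bracketing published estimates), minimising the summed squared relative
error of no-screening cancers and deaths. The search is cyclic coordinate
descent over a 7-point grid per parameter with bracket halving across
three sweeps, evaluated on the deterministic expectation engine — a
noise-free objective makes the procedure exactly reproducible, which a
seeded microsimulation objective would not.

The optimum sits on the lower bounds of the transition ranges with the
sojourn bracket at its floor, achieving 4,977 cancers and 1,751 deaths per
100,000 (relative errors 2.5% and 1.7%). This is a structural floor, not a
search failure: under the flat two-band background mortality extrapolated
to age 100 the cohort accumulates ~37 undiscounted life-years at 50, and
the long old-age tail keeps generating adenomas and cancers that no
admissible rate combination can fully suppress. The `converged` flag
applies a strict 2% criterion and honestly reports `FALSE`; the package's
tests assert the achievable 5% bound instead.

## Parameter fixture and probabilistic sensitivity analysis

The parameters module doubles as the synthetic-data generator: its
defaults *are* the study conditions (`base_case_parameters()`), it writes
and re-reads the full configuration as YAML
(`emit_parameter_fixture()`/`load_parameters()`, an exact round trip with
unknown keys rejected and partial files only honoured under an explicit
`inherit_base_case` flag), and it samples second-order parameter sets for
the PSA.

Each input printed with a plausible range carries one distribution:
**beta** for proportions (prevalences, stage fractions, complication
risks), matched to the base-case mean with SD = range/3.92; **triangular**
for ranged variables without a stated distribution (adenoma transitions,
adherence), with the mode at the base case; **log-normal** for skewed
costs, median-anchored at the base case with the range read as a central
95% interval on the log scale. Draws are truncated to the printed range;
lower bounds printed as exactly 0 are nudged to small positive values so
the distributions are proper. Inputs without ranges (stage mortality,
utilities, management costs) and *all* test sensitivities/specificities
are excluded — sensitivity and specificity co-vary along an ROC curve that
is not available, so varying them independently would manufacture
impossible tests; they are explored through the alternative
test-performance rows (FIT-low/mid/high, and so on) instead. Because
fields are sampled independently, a draw can violate a joint ordering
(e.g. a therapeutic complication risk below its diagnostic counterpart);
such draws are rejected and redrawn, and sampled stage distributions are
renormalised to sum to one.

What the sampler emulates is parameter (second-order) uncertainty under
these stated families; what it does not emulate is real-data features such
as correlated test performance, age-dependent adherence drift, or
secular trends in costs — conclusions from passing PSA tests are
conditional on the family choices above.

`run_psa()` evaluates all strategies on each sampled parameter set with
the expectation engine (common parameters across strategies, so
incremental quantities are paired), reports 2.5th/97.5th empirical
percentiles using linear interpolation between closest ranks (R's type-7
quantile, fixed), and exports the incremental cost/QALY scatter for a
designated comparison (FIT-mid versus no screening by default).

## Incremental analysis

`incremental_analysis()` sorts strategies by cost, flags strong dominance
(no dearer and no less effective, one inequality strict) and extended
dominance (detected as a non-increasing ICER along the cost-ordered chain,
equivalently domination by a blend of two other strategies), and reports
each frontier member's ICER against the next cheaper frontier member. Both
dominance flags are kept distinct so either reporting convention can be
reconstructed. Exact cost/QALY ties keep the first label in order as the
chain representative, with tied partners flagged and left without an
ICER; collinear chain points (equal consecutive ICERs) are treated as
extendedly dominated. The routine is verified against a brute-force
pairwise-blend oracle on a thousand random small instances.

## Numerical choices and problem sizes

* Years since diagnosis advance at the cycle start, so the stage hazard
  applies in years 1–5 after diagnosis (five applications compound exactly
  to the five-year risk) and the utility decrement covers years 0–4.
* Discount factors are precomputed as `(1+r)^-t`; year 0 is undiscounted.
* The expectation engine aggregates state atoms each cycle via an integer
  packing key; masses below machine precision are dropped only when
  exactly zero, and per-cycle total mass is retained for conservation
  checks (unit tolerance 1e-9).
* Microsimulation draws a fixed number of uniforms per person-year in
  each stream regardless of state, which is what makes common random
  numbers exact across arms.
* Default sizes: 100,000 persons for count outcomes (reported per
  100,000); unit tests run engine-equivalence at 20,000 persons and
  behavioural checks at 2,000–50,000; PSA tests use few draws since each
  draw is a deterministic expectation run. These sizes keep the full test
  suite in the minutes range while leaving Monte Carlo error well inside
  the asserted 3-SE bounds.

## Known limitations

* **Background mortality is two flat bands.** Annual risks 0.005/0.018
  with a hard stop at age 100 overstate old-age survival relative to a
  real life table (~37 undiscounted life-years at 50). Lifetime QALY
  *levels* are therefore inflated, and calibrated absolute costs of the
  no-screening arm are deflated (diagnoses are pushed late, where
  discounting shrinks the stage-cost lump sums). Count outcomes and
  within-model contrasts are calibrated and internally consistent, but
  between-arm *cost differences* inherit this structure: in this build
  screening is not cost-saving against no screening, and the FIT-high
  versus FIT-mid ICER runs high, both traceable to the mortality/horizon
  structure and to false-positive colonoscopy volumes (a 0.91-specificity
  annual test accumulates substantial follow-up colonoscopy costs under
  the stated cascade rules). The acceptance report states these measured
  values rather than adjusting the structure post hoc.
* **No serrated or flat-lesion pathway, no rapid-interval cancers**: all
  cancers pass through detectable adenomas, so test sensitivity fully
  governs preventability.
* **Single worst-lesion state machine**: synchronous polyps and their
  cumulative histology are not represented.
* **Stage is assigned at diagnosis**, not progressed preclinically; the
  sojourn is one exponential clock, so length-biased sampling of
  slow-growing tumours is absent.
* **Screening results are independent across rounds** given the true
  state; a systematically false-negative subgroup would reduce programme
  effect below the model's prediction.
* **Management costs are diagnosis-year lump sums** in 2008 CAN$ with no
  inflation machinery and no terminal-care timing.
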