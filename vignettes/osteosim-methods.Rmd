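---
title: "Model and methods behind osteosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind osteosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosim)
```

## The model

`osteosim` is a patient-level (microsimulation) cost-effectiveness model of
osteoporosis treatment. Individual patients are simulated from a starting
age (69 by default) until death or age 100 in six-month cycles. In every
cycle a patient is at risk of hip, clinical vertebral and wrist fractures
and of death, and accrues costs, utility and life years. Three strategies
are compared: 18 months of teriparatide, 18 months of an oral
bisphosphonate, and no treatment. Four cohorts are built in
(`default_cohorts()`): severe postmenopausal osteoporosis (PMO, T-score
-3.0, all women) and glucocorticoid-induced osteoporosis (GIOP, T-score
-2.5, 80% women), each either with an incident vertebral fracture six
months before baseline alone, or with an additional historical vertebral
fracture five years before baseline.

### Fracture risk

The per-cycle, per-type fracture probability is assembled from:

* a *baseline* annual first-fracture risk for Swedish women at
  population-mean BMD, tabulated at age-band midpoints (the 50--54 band is
  carried at age 52) and linearly interpolated between midpoints, clamped
  outside the table. Male risks are imputed by multiplying the female risk
  by an age-specific male:female ratio, capped at 1.
* a *BMD multiplier* `gradient^(t_mean(age) - t_measured)`, where the
  gradient is the relative risk per SD of BMD. The exponential-gradient
  form is a design choice (the functional form is not fixed by the
  sources); it gives multiplier 1 at the population mean and multiplies
  risk by the gradient per SD below it. The patient's measured T-score is
  fixed at baseline while the population mean declines with age, so the
  relative penalty shrinks as the cohort ages.
* a *history multiplier*: a fracture raises subsequent fracture risk for
  5 years (configurable, `history_window_years`). One in-window fracture
  of a type with relative risk `r` contributes `r`; a second in-window
  fracture of the same type escalates the increase by 50% in GIOP and
  100% in PMO, i.e. `1 + (1 + s)(r - 1)`; third and later same-type
  fractures reuse the second-fracture multiplier. Across types the
  largest multiplier applies.
* a *GIOP multiplier*, an age- and type-specific relative risk applied to
  GIOP patients only.
* the *treatment relative risk* (below).

The annual baseline converts to a six-month probability by the
complement-power rule `1 - (1 - p)^(1/2)` rather than division by two:
this is exact for a constant hazard and keeps probabilities in range near
the bounds. Multipliers then compose on the probability scale with a hard
cap at 1 (the default); setting `risk_composition = "rate"` composes them
on the hazard scale instead (`1 - exp(-h * m)`), which can matter when the
combined multiplier is large.

### Treatment

Teriparatide reduces vertebral fracture risk to RR 0.17 and non-vertebral
(hip and wrist) risk to RR 0.47 while on treatment. After completion or
cessation, a sustained benefit holds (vertebral RR 0.43 for 18 months;
hip/wrist RR 0.73 for 30 months) and then declines linearly to no effect
over a further 18 months. The bisphosphonate arm uses combined
oral-bisphosphonate relative risks held constant for the 18-month course
and ramped linearly back to no benefit over 18 months after cessation.
After *early* discontinuation the same post-treatment timeline is anchored
at the cessation cycle, with the full sustained and offset durations; no
proportional scaling by time on drug is applied (the sources are silent,
and anchoring keeps the timeline independent of the adherence path).

Discontinuation is a per-cycle persistence curve (probability of still
being on treatment at the start of each treated cycle, interpolated to
cycle boundaries from observational persistence data). A patient who
discontinues at the boundary after cycle *k* pays drug and monitoring for
cycles up to and including *k* only.

### Mortality

Two death causes compete each cycle, in a fixed order that matches their
timing conventions: fracture-related excess death is drawn first and is
taken to occur at the *start* of the cycle (nothing accrues); fractures
are then drawn; natural death is drawn last and occurs at the *mid-point*
of the cycle (half the cycle's costs, utility and life years accrue).
Natural mortality is life-table mortality with the fracture-attributable
proportion of deaths removed, which prevents double counting when the
excess term is added. Excess mortality applies after hip and vertebral
(never wrist) fractures as `m6(age, gender) * (multiplier - 1)`, where
`m6` is the base fracture-mortality probability series and the multiplier
declines from 2.5 in the first year to 1 at the phase-out horizon
(7 years for hip, 6 for vertebral); with both fracture types in the
window, the larger multiplier is used. Ages advance 0.5 years per cycle
and all lookups use age at cycle start.

### Costs

* Drug: daily price times days per cycle (182.625 = 365.25/2 by default;
  configurable — the sources do not state the convention, and the choice
  moves per-cycle drug cost by well under 1%).
* Monitoring: one physician visit per treated cycle; the BMD-inclusive
  price (EUR 201) in treated cycles 1, 3, 5, ... and the basic price
  (EUR 194) otherwise, so an adherent 18-month course has 3 visits.
  The no-treatment arm accrues no visits (taken as untreated and
  unmonitored; the sources are silent).
* Fractures: an acute six-month cost in the event cycle, in full even in a
  death cycle (the fracture precedes death in the event order); hip and
  vertebral fractures then add a lifetime six-month continuing cost
  (nursing-home care for hip, analgesics for vertebral; wrist has none).
  A repeat fracture pays acute again but its continuing cost *supersedes*
  the existing entry only upward (`max`), so long-term care is never
  double counted. Prevalent (pre-baseline) hip/vertebral fractures enter
  the continuing-cost map at baseline prices; this is identical across
  arms and cancels from every increment.

Costs and QALYs are discounted at 3% per year, applied per cycle as
`(1 + r)^(-0.5 * cycle)`; there is no mid-cycle discounting refinement.
Life years are reported undiscounted.

### Utilities

Utility in a cycle is the age-interpolated base utility (0.84 through age
50 down to 0.65 at 85) times the product over fracture types of that
type's current multiplier. A type contributes its first-year multiplier
during the event cycle and the following cycle (a cycle-consistent reading
of "first year"), and its subsequent multiplier from then on for the rest
of life. Lifetime persistence mirrors the treatment of continuing costs;
a prevalent fracture five years before baseline therefore still depresses
utility at entry, while the incident fracture six months before baseline
enters in the second cycle of its first year.

For a repeat fracture of the same type the default first-year multiplier
is `m_first * (1 - q (1 - m_sub))` with `q = 0.25`: the repeat event
carries its full first-year decrement plus a quarter of the residual
disutility attributable to the previous fracture's subsequent multiplier.
The quoted rule admits a second, additive reading
(`m_first - q (1 - m_sub)`), available via
`params$utility$repeat_rule = "additive"`; the two differ by under one
percent of utility for the packaged multipliers, but both are kept because
the sentence defining the rule is genuinely ambiguous.

## Randomness and replication

One seedable generator drives everything. `run_cohort()` derives one seed
per replication; within a replication the gender assignment and six
uniform-draw matrices (excess death, three fracture types, natural death,
discontinuation) are generated once and *shared across arms* — common
random numbers. Arms therefore differ only through treatment-dependent
quantities, and with treatment neutralized all arms coincide exactly (a
tested invariant). Draws are consumed positionally from the matrices, so
the stream does not depend on the arm or on how many patients remain
alive. Gender is Bernoulli per patient by default
(`gender_assignment = "stratified"` fixes the split exactly).

## The parameter bundle and its placeholder tables

`default_parameter_set()` assembles the packaged bundle. Quantities
printed in the primary sources are carried exactly: the unit costs
(EUR 14.74 and 0.42 per day; EUR 201 and 194 per visit, all derived in
code from their SEK amounts at 9.0335 SEK/EUR), the teriparatide efficacy
timeline, the excess-mortality schedule anchors, the base-utility anchors,
the first-year vertebral (0.626) and subsequent hip (0.813) utility
multipliers, discount rates, cycle structure and cohort definitions.

Everything else — baseline risk tables, male:female ratios, GIOP relative
risks, mean T-score by age, age-banded fracture costs, life tables,
attributable-death proportions, the fracture-mortality series between its
two quoted anchors, discontinuation curves, bisphosphonate efficacies and
the remaining utility multipliers — comes from supplementary source tables
that are not shipped. These are *generated placeholders*
(`generate_placeholder_tables()`): field-plausible anchor points
interpolated with a seeded, monotonicity-preserving jitter, bit-identical
for a fixed seed, flagged `provenance = "placeholder"`, and swappable for
a user bundle via `write_parameter_set()` / `load_parameter_set()`. Every
simulation result carries the list of placeholder tables it used.

What this means for interpretation: structural behaviour (CRN identities,
life-table calibration, ledger arithmetic, dominance handling,
monotonicity in efficacy) is fully testable against the placeholder
bundle, and the base-case comparisons come out directionally and in
magnitude where the published analysis sits (ICERs in the tens of
thousands of euros per QALY, GIOP below PMO, two-fracture below
one-fracture). Reproducing the published headline numbers to their
printed precision, however, requires the full supplementary input tables;
the placeholder bundle cannot and does not claim to do that.

## Sensitivity analyses

`one_way_sa()` reruns the paired comparison with one parameter at its low
and high value, same seeds throughout, and sorts by ICER range width
(tornado order). Any dotted parameter path can be varied, including whole
efficacy profiles.

`run_psa()` samples, per simulation, fracture-cost scale factors
(lognormal, mean at baseline, support 50%--200% of baseline), fracture
utility multipliers (beta rescaled to stated ranges, mean at baseline) and
on-treatment relative risks (beta within trial confidence intervals; the
pooled non-vertebral RR is drawn once and applied to hip and wrist
together), then runs one paired comparison per draw under common random
numbers within the draw (a variance-reduction choice; the sources do not
state it). The lognormal spread is set so `exp(mu +/- 1.96 sigma)` spans
the support — symmetric on the log scale only — and draws are truncated to
the support by rejection; with the mean pinned at baseline the truncated
mean is exactly the baseline. The beta concentration is set so two
standard deviations span the range, guarded near the support edges (a
baseline within 0.1% of an edge degenerates to the baseline).

The acceptability curve follows the share definition: the fraction of
draws with positive incremental QALYs that are either cost-saving
(dominant, always acceptable) or have cost-per-QALY below the
willingness-to-pay value; draws with non-positive incremental QALYs are
never acceptable. This keeps the curve monotone non-decreasing. A net
monetary benefit variant (`method = "nmb"`) is provided, since NMB is the
more standard construction; the two coincide whenever no draw has negative
incremental QALYs.

## Numerical and degenerate-input conventions

* Zero baseline risk gives zero fracture probability under any
  multipliers; zero mortality gives full-accrual cycles to the age cap.
* The five-year history window is inclusive: an event exactly five years
  old still counts (so the historical fracture in the two-fracture cohorts
  is active at baseline and expires as the simulation proceeds).
* The excess-mortality schedule is indexed by completed years since
  fracture (`floor(years) + 1`), so "year 1" covers the first two cycles.
* Degenerate PSA supports (min = max = baseline) return the baseline and
  reproduce the base case exactly under the same seeds (tested).
* Currency conversions round to the precision at which each unit cost is
  quoted (cents for daily drug costs, whole euros for visit prices), so
  the published values are reproduced exactly.

## Problem sizes

Default runs in the examples and the acceptance script use 8 replications
of 10,000 patients per cohort for base-case outputs and 200 simulations of
500 patients for the PSA; the life-table calibration check uses a single
replication of 100,000 patients. These sizes hold Monte Carlo error on
ICERs to a few percent while keeping a full run in about a minute on one
core; the engine itself is vectorized across patients and scales linearly,
so the published analysis scale (200 x 100,000, and 1,000 x 1,000 for the
PSA) is a matter of runtime only.

## Known limitations

* The placeholder tables are plausible, not sourced; absolute outputs
  under the packaged bundle are illustrative until a complete user bundle
  is supplied.
* Only hip, clinical vertebral and wrist fractures are modelled; no
  side-effect costs, societal costs, or treatments beyond the three arms.
* The T-score is a single fixed entry value per cohort, not a
  distribution, and does not evolve with treatment.
* Excess mortality multiplies the base fracture-mortality series, not
  all-cause mortality; the wiring in the sources is terse and this reading
  is flagged in the mortality module documentation.
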