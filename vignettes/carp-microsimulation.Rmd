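---
title: "Projecting coronary revascularization demand with a CHD/CARP microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting coronary revascularization demand with a CHD/CARP microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(carpsim)
```

## The model

carpsim simulates a population cohort aged 35–79 through calendar years
2001–2010 to project demand for coronary artery revascularization
procedures (CARPs): bypass surgery (CABG) and percutaneous coronary
intervention (PCI). Each member occupies one of four mutually exclusive
CHD/CARP history states — no history, CHD admission without a CARP, PCI
without CABG, CABG ever — ordered by dominance so that state only moves
upward. Five annual events are recognised: CHD admission without a CARP,
CABG, PCI, CHD death and non-CHD death; the two deaths are absorbing.
Annual event risks are stratified by calendar year, sex, 5-year age band
and history state, and the residual mass `1 - sum(risks)` is "no event this
year".

The model is discrete-time with a one-year cycle. Assumptions worth
stating explicitly:

* risks depend on the person only through (sex, attained age band, current
  state) — there are no individual risk-factor covariates;
* persons are independent; there are no capacity constraints on procedures;
* mortality competes with the other events once per year (first draw); it
  is not re-drawn after a within-year procedure;
* a person is removed at attained age 80, at death, or at the end of the
  horizon, whichever comes first.

## The within-year sub-cycle

The published description of this model class allows, within one year, a
CHD admission without a CARP, up to two admissions with CARPs, and
possible death, but the exact sub-cycle ordering is not printed anywhere we
could follow. carpsim therefore fixes one explicit, documented rule and
isolates it behind `simulate_person_year()` so alternatives can be swapped:

1. one categorical draw over {five events, none} at the current state's
   risks;
2. death terminates the person immediately (death is always the last —
   and then only — event of the year);
3. a CHD admission updates the state (`NO_HISTORY → CHD_NO_CARP`) and
   permits one follow-on draw over {CABG, PCI, none};
4. every CARP updates the state immediately (CABG always to
   `CABG_HISTORY`; PCI to `PCI_NO_CABG` unless CABG history exists) and,
   while fewer than two CARPs have occurred, permits a further follow-on
   draw over {CABG, PCI, none} at the *updated* state's risks;
5. after two CARPs, or a "none" follow-on, the year ends; age increments.

Updating the state immediately is the only reading under which follow-on
draws are well defined for a no-history person (their first-ever PCI
plausibly changes the within-year probability of a subsequent procedure).
Because mortality acts only in the first draw, annual death risk is never
double-counted.

`expected_counts()` is the deterministic twin: it enumerates exactly this
outcome tree (at most first draw × two follow-ons) per person-year and
propagates the end-of-year state distribution, so engine and oracle agree
*in expectation by construction*, not approximately. The test suite checks
the oracle itself against an independently coded exhaustive path
enumeration on small cohorts (agreement to 1e-12) and the engine against
the oracle statistically.

## Random numbers and reproducibility

Replicate `r` of `run_replicates()` uses a substream seed drawn once from
the master seed, so results are bit-reproducible from (inputs, master
seed, replicate count). Within a replicate-year the engine draws three
uniform vectors over *all* cohort members — dead ones included — in fixed
order; person `i` consumes `u1[i]`, `u2[i]`, `u3[i]` for the first draw
and the up-to-two follow-ons whether or not they are needed. Uniform
consumption therefore never depends on outcomes, which buys two things:
the vectorized engine is deviate-for-deviate identical to the scalar
reference implementation, and scenarios run under one master seed use
common random numbers — identical deviates at identical person-year-stages
— so scenario contrasts reflect risk changes, not Monte Carlo noise. A
scenario that modifies nothing reproduces the Base run bit-for-bit.

## Trend fitting, projection and scenarios

Trends are fitted by ordinary least squares on the *probability* scale to
the 1998–2000 risks of each cell, because the modelled quantity is a
linear trend in the risks themselves; clamping to `[floor, cap]`
(defaults 0 and 1) at projection time handles boundary violations, and
every clamping event is logged with its cell identity in the `"clamping"`
attribute. Logit-scale fitting was considered and rejected as the default
since it changes the meaning of "the linear trend continues"; the fit is
cheap to redo on transformed inputs if a user wants it. With three
observed years the fitted value at the reference year can in principle
fall slightly outside `[0, 1]` for extreme inputs; it is deliberately not
clamped at fit time (projection clamps), keeping the fitted line intact.

Two genuinely open readings are resolved as follows, each switchable:

* **Scale scenarios multiply the trend-projected trajectory**, not a
  flat year-2000 level. "Increased by 10% while the trends in other risks
  continue" reads most naturally as a perturbation of the Base projection.
* **`level_off` holds the fitted year-2000 value**, consistent with using
  the fitted line for everything else; `apply_scenario(...,
  level_off_source = "observed")` switches to the raw observation.

Whether the original analysis fitted by least squares or drew a line
through the 1998 and 2000 endpoints is not stated; least squares is the
defensible default and collinear inputs make the two identical.

The five built-in scenarios (`builtin_scenarios()`) act on the no-history
state only: `base` (no modification), `incidence1` (level-off CHD
admission), `incidence2`/`incidence3` (+10%/+20% CHD admission),
`incidence4` (+20% CHD admission, +5% PCI, level-off CABG and CHD death).

## The synthetic-data generator

The real inputs — risk estimates from linked hospital records and the
census-based baseline state distribution — are not publicly available, so
`generate_cohort()` and `generate_risk_history()` provide synthetic
stand-ins with the qualitative structure the analysis assumes. All risks
follow an inverse-logit model

```
plogis(alpha_event + 0.08 (band_mid - 55) + 0.5 [male] + state_effect
       + gamma_event (year - 2000) + N(0, 0.02))
```

with calendar slopes `gamma` of −0.03 (CHD admission), −0.05 (CABG),
+0.06 (PCI), −0.04 (CHD death), −0.01 (non-CHD death): the declining
incidence components and the rising PCI risk. Intercepts are chosen so
that the CHD-admission risk dominates the CABG component in every cell and
competing sums stay below 1; the state offsets apply to the four
CHD-related events and are zero for non-CHD death, which we take to be
independent of cardiac history. Cohort ages follow linearly decreasing
5-year-band weights (9:1 from 35–39 to 75–79, a stylised adult age
pyramid), and history prevalence follows
`plogis(-6 + 0.07 age)` split 0.5/0.3/0.2 among CHD-only, PCI and CABG
history — a prevalence rising from under 1% at 35 to roughly 8% at 79,
plausible orders of magnitude for an industrialised population. Noise is
applied on the logit scale so probabilities stay in (0, 1) by
construction.

These coefficients are calibrated only to qualitative statements —
declining versus rising, dominance, age and sex gradients. They are *not*
estimates of any real population's risks, and passing tests on synthetic
data demonstrate correctness of the machinery, not fidelity of projected
counts: synthetic totals (hundreds of CABGs for a 10,000-person cohort
over a decade) are not comparable to published totals for a
million-person state population. What does carry over to real data is
every structural property the tests pin down: conservation, monotonicity
of totals in risks, engine–oracle agreement, determinism, and the
qualitative scenario ordering (the combined incidence4-style scenario
dominating the level-off-only one).

## Numerical and degenerate-input choices

* Risk tables with a competing-event sum above 1 are *rejected* (at
  validation, projection and simulation time), never renormalized —
  silent renormalization would hide input errors.
* Categorical draws use the convention `category = 1 + #{cumulative
  thresholds <= u}` with strict `<` on the left boundary, so degenerate
  probabilities 0 and 1 behave exactly (a zero-probability event is never
  drawn, a probability-1 event always).
* The expectation oracle conserves person-mass to ~1e-12 over a 10-year
  horizon (alive + died + aged-out = cohort size at every year boundary).
* Missing risk cells abort simulation naming the (year, sex, band, state,
  event) cell; a lookup at an age outside 35–79 is a domain error.
* CSV writers emit probabilities with 17 significant digits so that
  write→read round trips are bit-exact.

## Problem sizes

The packaged analyses and checks use a 10,000-person synthetic cohort with
100 replicates over 2001–2010 (a few seconds per scenario set), which
gives replicate-mean standard errors small enough that every (year, event)
cell is resolved against the oracle at 5 estimated standard errors.
Smaller cohorts (200–2,000) back the property-style tests; the exhaustive
path-enumeration cross-check runs on ≤3 persons × ≤3 years where the full
outcome tree is tractable.

## Limitations

* The within-year ordering is a documented stand-in for an unpublished
  sub-cycle diagram; all conclusions that depend on fine within-year
  sequencing should be read with that in mind.
* Whether CHD death outside the no-history state should be conditioned on
  having no CHD admission the same year is ambiguous in this model class;
  carpsim treats CHD death as one of the competing first-draw outcomes.
* No risk-factor submodel: scenarios act directly on event risks, not on
  blood pressure, cholesterol, obesity or diabetes prevalence.
* Trend extrapolation is linear on the probability scale over a 10-year
  horizon from a 3-year window; it is a scenario device, not a forecast
  with uncertainty intervals (replicate variance captures only Monte
  Carlo noise, not trend uncertainty).
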