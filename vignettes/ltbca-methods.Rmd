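---
title: "Modelling lead-time-biased case ascertainment: methods and design notes"
author: "ltbca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lead-time-biased case ascertainment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltbca)
```

## The model and its assumptions

`ltbca` quantifies how differential screening uptake between strata of a risk
factor distorts case ascertainment in an observational study, under a *joint
null*: neither the risk factor nor screening affects the underlying disease
process. Any departure of the simulated relative risk from 1 is therefore
pure ascertainment bias, usable as a correction factor.

The generative model is a progressive-disease natural history with a
counterfactual comparison:

1. **Onset.** Detectable preclinical disease begins at age $x$ with intensity
   $w(x)$ per person-year. $w$ is unobservable; it is obtained by fitting a
   continuous curve to *clinical* age-specific incidence rates and shifting it
   backward by the mean sojourn time, separately for the calendar period
   before the study and the period during it (two curves, $w_b$ and $w_d$,
   each an average over its period).
2. **Sojourn.** The preclinical duration $T$ has a lognormal density $f$,
   strictly positive, parameterised by its mode and standard deviation in
   years. The counterfactual symptomatic diagnosis age is $z = x + T$.
   Optionally $f$ is a two-component mixture whose minor component has a very
   long sojourn (default mode 20 y, sd 3 y, weight 0.2): screen detection of
   those individuals is overdiagnosis in the modelled horizon.
3. **Screening.** Within each risk stratum and period, behaviour is
   summarised by step functions of age: $k_1(x)$, the proportion ever
   screened, and $k_2(x)$, screens per year among screeners. Screening starts
   no earlier than `screenage`. Each screen detects an existing preclinical
   case with constant sensitivity $\xi$; over an age interval carrying an
   expected $N = \int k_2$ screens, a screener escapes detection with
   probability $(1-\xi)^N$.
4. **Ascertainment.** A case enters the study window $[a_0, a_E)$ of its age
   stratum either symptomatically ($z$ in the window, not screen-detected
   earlier) or by screen detection inside the window.

The counterfactual unscreened cumulative incidence $G_U$ integrates
$w \cdot [F(a_E - x) - F(a_0 - x)]$ over onset ages ($F$ the sojourn CDF).
The screening-adjusted cumulative incidence is
$G_S = G_U + \mathrm{part}_1 + \mathrm{part}_2 - \mathrm{part}_3$:

* $\mathrm{part}_1$ — onset before $a_0$, escaped pre-window screens,
  screen-detected in the window, $z \in (a_E, \mathrm{maxage}]$: added cases;
* $\mathrm{part}_2$ — the same with onset inside the window: added cases;
* $\mathrm{part}_3$ — onset and screen detection before $a_0$,
  $z \in (a_0, a_E]$: removed cases.

Age strata are aggregated with birth-cohort weights $\omega_i$, and the bias
RR is $G_S(\text{exposed})/G_S(\text{unexposed})$.

Key assumptions: incidence and sojourn are identical across risk strata (the
null); sojourn is age-invariant within a scenario; screening behaviour is
exchangeable within a stratum-period-age bin; no competing mortality and no
effect of screening on incidence or survival.

## Parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| sojourn mode | years | 5 | centre of the 1/3/5/10 sensitivity grid |
| sojourn sd | years | 3 | centre of the 1/3/5 grid |
| sensitivity $\xi$ | per screen | 0.46 | low end of published chest x-ray sensitivities (0.46/0.66/0.86 grid) |
| `screenage` | years | 40 | age from which screening plausibly begins |
| `maxage` | years | 100 | horizon for counterfactual diagnoses; sojourn mass beyond it is negligible except for the overdiagnosis component, which is the point |
| overdiagnosis weight | — | 0.2 | nominal long-sojourn share of the preclinical-case population |
| overdiagnosis mode/sd | years | 20 / 3 | long enough that most counterfactual diagnoses fall outside the horizon |
| quadrature step | years | 0.05 | see numerical choices |
| age strata | — | four 5-y strata, 55–74 entry | typical cancer-screening-trial enrollment span |

## What the synthetic generator emulates — and what it does not

All inputs are generated by the `fixtures` functions; nothing is downloaded.

* `make_incidence_fixture()` produces 5-year banded rates (0 to 85+), two
  periods, from a log-cubic truth curve rising from near zero in the young to
  a peak of ~500 per 100,000 person-years near age 77 — the characteristic
  adult lung-cancer shape of long-standing registry averages. The during
  period is scaled to 0.9 of the before period, emulating a mild secular
  decline. Truth parameters are recorded for recovery tests.
* `make_screening_fixture()` encodes the structural feature that drives the
  bias: the `"biased"` preset gives the exposed stratum a modest pre-study
  screening advantage (k1 0.45 vs 0.35; k2 0.7 vs 0.6 screens/y) and a large
  during-study one (0.70 vs 0.30; 1.0 vs 0.5), mimicking a trial whose
  protocol concentrates the screening differential inside the study period.
  `"null"` makes the strata identical; `"intervention-like"` widens the gap.
* `make_weights()` returns uniform birth-cohort weights by default, with a
  stratum-specific option.

These fixtures reproduce the *structure* of registry tables and trial
questionnaire summaries, not any real population's values. Passing tests
demonstrate internal correctness of the integrals, the microsimulation and
the correction logic under realistic shapes and magnitudes; they do not
validate the bias magnitudes against any actual study, whose participant-level
screening behaviour would be needed as input. Real data would also bring
features the generator omits: cohort effects beyond the two-period split,
age-varying sojourn, correlation between screening behaviour and unmeasured
risk, and screen-detected cases already embedded in registry incidence.

## Numerical choices

* **Inner integral by CDF differences.** $\int_a^b f(z-x)\,dz =
  F(b-x) - F(a-x)$ removes one quadrature dimension exactly.
* **Outer quadrature.** Composite Simpson with step 0.05 y. The integrands
  step at screening-bin edges and kink at `screenage`, so the domain is split
  at those knots and each panel integrated separately; panel endpoints are
  nudged inward by a relative $10^{-9}$ so half-open step functions are
  sampled on their own side of a jump. Halving the step then changes $G_U$
  and $G_S$ by under $10^{-6}$ relative (enforced by a test).
* **Mode/sd to lognormal parameters.** Substituting the mode constraint
  $\mu = \log m + \sigma^2$ into the variance identity leaves
  $(e^{\sigma^2}-1)e^{3\sigma^2} = (s/m)^2$, strictly increasing in
  $\sigma^2$; solved by bisection to near machine precision. Round-trip error
  is below $10^{-6}$ across the whole parameter grid.
* **Curve fitting.** Least squares on the log-rate scale at band midpoints
  (linear in the log-cubic coefficients); the open-ended 85+ band is attached
  to its lower edge plus 2.5 y. Zero-rate bands are dropped with a warning
  (log undefined); at least four positive points are required. A rate-scale
  refit via Levenberg–Marquardt (`minpack.lm`) is available, started from the
  log-scale solution — plain Gauss–Newton stalls in the zero-residual case of
  noiseless points.
* **Degenerate inputs.** $a_0 = a_E$ windows, weights not summing to 1,
  sensitivities outside $[0,1]$ and inconsistent survey counts are rejected
  at construction; $\xi = 0$ or $k_1 \equiv 0$ short-circuits to
  $G_S = G_U$ bit-for-bit; a zero denominator makes the RR a degenerate-
  scenario error rather than `Inf`.
* **Onset sampling (microsimulation).** Inverse-CDF on a 0.01-y trapezoid
  grid with the window opening forced onto the grid, so the before/during
  intensity discontinuity is represented exactly.

## Design decisions at genuinely open points

* **Geometric escape as default.** The bracketed screening-rate integral in
  the adjusted-incidence formula is dimensionally an expected *count* of
  screens, not a probability. Independent screens at fixed sensitivity give
  the geometric escape law $(1-\xi)^N$, which reduces to the linear reading
  $1-\xi N$ to first order; the linear form is kept as a clamped option
  (`detection_form = "linear"`, detection $\min(1, \xi N)$ — defined so that
  $\xi = 0$ detects nothing, which the alternative reading
  $\min(1,(1-\xi)N)$ would violate).
* **Detection needs detectable disease.** The lower bound of every detection
  integral is $\max(x, \mathrm{screenage}, \text{interval start})$: a person
  cannot be screen-detected before preclinical onset, whatever the nominal
  bounds of the screening period.
* **Escape-before form.** The added-incidence term multiplies an
  escape-before factor by a detect-during factor. The default treats
  non-screeners as escaping trivially,
  $(1-k_{b1}) + k_{b1}(1-\xi)^{N_b}$ (`line1_form = "complement"`); the
  literal product $k_{b1}(1-\xi)^{N_b}$, which implicitly conditions on
  being a pre-study screener, is available as `"literal"`.
* **$G_S$ includes the baseline.** The adjusted cumulative incidence is
  defined as baseline plus the screening delta, so no screening gives
  $G_S = G_U$ exactly and identical behaviour across strata gives RR = 1
  identically — the self-consistency requirements of a bias model.
  `gs_includes_baseline = FALSE` returns the delta alone.
* **Horizon.** Counterfactual diagnoses beyond `maxage` are excluded from the
  added-incidence accounting: screen detection of such cases is
  overdiagnosis, tracked separately by component tagging rather than counted
  as in-window incidence.
* **Microsimulation screen process.** The default draws per-person detection
  as a single Bernoulli with the exact geometric escape on the real-valued
  expected screen count — the same estimand as the analytic form, so
  oracle-versus-integral differences are purely binomial Monte Carlo error. A
  `"poisson"` option draws discrete screen counts (escape $e^{-\xi N}$ in
  expectation), bracketing the continuous-rate ambiguity; the two agree to
  first order in $\xi N$ and are compared in a test.
* **Realized overdiagnosis denominator.** The nominal mixture weight is a
  share of the *preclinical-case* population (sojourns are attached to
  onsets), so the realized overdiagnosed fraction is reported among persons
  with preclinical onset: weight × P(screen-detected | long component). This
  makes the limiting behaviours correct — it approaches the nominal weight
  under universal, perfectly sensitive screening and zero under no screening.
* **Age-invariant sojourn.** One (mode, sd) per scenario; age dependence is
  plausible biologically but is left to the sensitivity grid over modes and
  sds rather than modelled within a scenario.

## Problem sizes

The deterministic model at step 0.05 y evaluates a full two-stratum,
four-age-stratum scenario in well under a second; the 72-cell sensitivity
grid runs in a few seconds. Microsimulation checks use 200,000 persons per
risk stratum (the package's standard oracle size; per-cell unit checks use
40,000), at which the binomial 3-SE bands are roughly 4–10% of the quantities
compared.

## Known limitations

* The bias RR is deterministic given inputs; no uncertainty in the fitted
  incidence curve or the behaviour tables is propagated.
* Registry incidence already contains screen-detected cases; where screening
  practice changed sharply inside the ascertainment period, the fitted
  "clinical" curve is itself distorted in a way the model does not undo.
* Correction of a 2×2 table by a single RR assumes the bias acts
  proportionately on all cases; systematic variation would need further
  stratification of the model.
* No competing mortality, no effect of screening on incidence or survival,
  and no calendar-time bookkeeping beyond the before/during split.
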