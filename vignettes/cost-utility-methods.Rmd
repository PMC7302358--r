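---
title: "Cost-utility modelling of food thickening in post-stroke dysphagia: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility modelling of food thickening in post-stroke dysphagia: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysphagiaCE)
```

## The decision problem

Dysphagia is a frequent stroke complication; patients who tolerate semisolid
food but aspirate fluids (GUSS screening band 10–14) are at elevated risk of
aspiration pneumonia (AP), which carries treatment costs, a quality-of-life
decrement and excess mortality. Thickening fluids with a xanthan-gum powder
is assumed to remove fluid aspiration without changing how long dysphagia
lasts. `dysphagiaCE` implements two decision-analytic models that price this
trade-off from the public payer's perspective (PLN), comparing thickener
treatment against routine clinical practice (postural and behavioural
compensation only):

* a **static model** — a closed-form expected-value calculation over a fixed
  8-week dysphagia episode, with at most one AP episode per patient; and
* a **dynamic model** — a weekly-cycle Markov cohort model over one year
  with dysphagia resolution, deterioration (onset of aspirations), a 2-week
  AP tunnel, and background stroke mortality.

Running both is a robustness device: if two structurally different models
agree on the incremental cost-utility ratio (ICUR), the conclusion does not
hinge on either structure.

## The static model

Each arm is an expected value over the 8-week episode. With
$p_a$ and $p_n$ the 8-week AP risks of aspirating and non-aspirating
patients (entered as the exact source fractions $10/82$ and $1/57$),
$U_a = 0.15$ and $U_n = 0.37$ the dysphagia utilities with and without
aspiration, $\Delta U_{AP} = 0.13$ the AP disutility over its 2-week
episode, $C_{AP} = 1924$ PLN the AP episode cost and $C_T$ the thickener
course cost:

$$
\begin{aligned}
C_{int} &= C_T + C_{AP}\, p_n, &
\mathrm{QALY}_{int} &= U_n \tfrac{8}{52} - \Delta U_{AP} \tfrac{2}{52} p_n,\\
C_{comp} &= C_{AP}\, p_a, &
\mathrm{QALY}_{comp} &= U_a \tfrac{8}{52} - \Delta U_{AP} \tfrac{2}{52} p_a,
\end{aligned}
$$

and $\mathrm{ICUR} = \Delta C / \Delta \mathrm{QALY}$. The course cost uses
the mean daily consumption of 37.96 g over 56 days at 77.05 PLN per 175 g
tin, with fractional tins (no rounding up to whole tins — rounding would
overstate the cost of an average course). The payer price excludes the
patient's 3.20 PLN flat copayment. Monitoring visits are deliberately not
costed here: over 8 weeks at most two would occur and their cost nearly
cancels between arms. There is no discounting over an 8-week horizon.

```{r static}
cfg <- base_case_fixture()
static_cea(cfg$static)
```

## Parameter estimation

The estimation module contains the formulas that turn source counts and
intervals into model inputs.

* **Cumulative risk to weekly rate.** Under a constant hazard,
  $IR = -\ln(1-CR)/T$ with $T$ in weeks; `pooled_incidence_rate()` averages
  per-study rates weighted by the number of patients. The pooled weekly AP
  rate in patients without dysphagia is 0.4036%/week in the base case.
* **Relative risks.** `relative_risk()` uses the ratio of proportions with
  the Katz log-normal interval,
  $SE(\log RR) = \sqrt{1/a - 1/n_1 + 1/b - 1/n_2}$. From the source 2×2
  counts this gives 8.27 (95% CI 3.28–20.85) for dysphagia with aspirations
  and 2.77 (1.03–7.42) without, both versus no dysphagia.
* **Rate to transition probability.** `weekly_probability()` applies the
  relative risk on the hazard scale, $p = 1 - e^{-IR \cdot RR}$. At these
  magnitudes this is numerically indistinguishable from multiplying
  probabilities, but it can never produce $p > 1$.
* **Distribution back-calculation.** `sd_from_interval()` recovers an SD
  from a symmetric normal interval, $(high-low)/(2z)$; `beta_from_moments()`,
  `gamma_from_moments()` and `lognormal_from_ci()` convert moments or
  intervals into the sampling distributions used by the probabilistic
  analysis.

## The dynamic model

Eight states: no dysphagia, dysphagia without/with aspirations, AP weeks 1
and 2 (tunnel states tagged by the originating dysphagia state), and death.
The cohort cycles weekly for 52 weeks. Competing risks within a cycle are
applied multiplicatively in a fixed order — death first, then AP onset among
survivors, then resolution/deterioration among event-free survivors — so
every row of the transition matrix sums to one by construction (and is
asserted to $10^{-9}$ at run time).

Structural choices, made where the published description left the design
open:

* **Starting states.** The modelled population aspirates fluids, so the
  comparator cohort starts (and, absent resolution, stays) in dysphagia
  *with* aspirations; the intervention cohort starts in dysphagia *without*
  aspirations, because thickening is assumed to remove fluid aspiration and
  nothing else. Deterioration (0.11%/week) moves non-aspirating patients to
  the aspirating state — in effect, treatment failure.
* **No AP pathway after resolution.** Patients whose dysphagia resolves face
  background mortality only. The baseline AP rate of patients without
  dysphagia enters the model solely as the reference hazard that the
  relative risks scale; pricing baseline AP episodes in both arms would add
  equal cost to each and cancel from the increment.
* **Tunnel rules.** The AP episode lasts exactly two weeks; its cost is
  charged once on entry; resolution and deterioration are suspended during
  the episode; survivors return to the state they came from. Weekly death
  probability inside the tunnel is the background hazard scaled by the AP
  mortality relative risk (2.99) on the rate scale, capped at 1.
* **Cost accrual.** The weekly thickener cost (37.96·7/175·77.05 ≈ 117 PLN)
  accrues for every week spent in a dysphagia state — including tunnel
  weeks, since AP does not end the dysphagia — in the intervention arm only.
  Monitoring (186 PLN) is charged at weeks 1, 4, 12, 26, 39 and 52 to
  patients currently in a dysphagia state, in both arms; patients whose
  dysphagia has resolved are assumed discharged from the monitoring
  programme.
* **No half-cycle correction, no discounting.** QALYs and costs use
  end-of-cycle occupancy; with weekly cycles the half-cycle bias is far
  smaller than any parameter uncertainty, and a one-year horizon leaves
  nothing to discount. (An annual discount rate would matter only for a
  lifetime extension, which this package does not model.)

### Mortality

Weekly background mortality is piecewise constant at three levels: 4.60%
(weeks 1–4, covering the first 30 days), 0.96% (weeks 5–13, days 31–90) and
0.24% (weeks 14–52). The 30/90-day boundaries are mapped to the nearest
whole weeks because the model cycles weekly. As a scenario alternative,
`fit_log_survival()` fits $M(t) = a\ln t + b$ to cumulative-mortality time
points by ordinary least squares and `log_fit_mortality_schedule()` converts
the fitted curve into conditional weekly probabilities.

### Dysphagia resolution: calibration

The weekly resolution probability is calibrated to prevalence anchors
(fractions of surviving patients still dysphagic at given days after
stroke), assuming linearity between anchors: prevalence is interpolated on
the weekly grid (week $w$ ↔ day $7w$) and the week-$w$ resolution
probability is the one-step ratio $1 - \mathrm{prev}(w)/\mathrm{prev}(w-1)$,
clamped to $[0,1]$. A zero-prevalence anchor at day 365 is appended when
absent, encoding the assumption that no patient still has dysphagia after
one year. By construction, re-simulating the calibrated schedule reproduces
the anchor prevalences exactly (`simulate_prevalence()` and the round-trip
property tests exercise this).

### Placeholder inputs

Two dynamic-model inputs have no published main-source base value (their
source data sit in supplementary material not shipped here): the prevalence
anchors and the utility of resolved dysphagia. The fixture ships clearly
flagged synthetic placeholders — anchors 1.0/0.5/0.25/0.08 at days
0/7/28/180, chosen once so the implied expected dysphagia duration is about
five weeks (consistent with the published per-arm thickener spend), and
$u_{\textrm{no dysphagia}} = 0.46$, a plausible average post-stroke utility
on the same instrument scale as the dysphagia utilities. They are listed in
the fixture's `assumed_fields`; dynamic-model outputs under these
placeholders are indicative only and are nowhere asserted against published
numbers.

```{r dynamic}
dynamic_cea(cfg$dynamic)
```

## Sensitivity analyses

**One-way (tornado).** Each parameter is set in turn to its lower and upper
bound with all others at base, and the model is fully re-evaluated. Bounds
use published intervals where stated — 0.135–0.165 for the aspirating
utility, 0.32–0.42 for the non-aspirating utility, 0.10–0.15 for the AP
disutility — and exact (Clopper–Pearson) 95% binomial intervals from the
source counts for the two AP risks, which have no published interval. Rows
sort by decreasing ICUR span, ties broken alphabetically so output is
deterministic.

**Scenarios.** `scenario()` re-evaluates under named overrides: AP cost
multipliers, monitoring on/off, a shortened horizon, the log-fit mortality
schedule, or life-years-only effectiveness (all living-state utilities set
to 1 and the AP disutility to 0, so only survival differences count).

**Probabilistic.** Each iteration draws all parameters independently:
utilities and probabilities beta (utility SDs back-calculated from their
intervals; AP risks $\mathrm{Beta}(x,\,n-x)$ from their binomial counts),
relative risks log-normal from their published CIs, and costs gamma with SD
set to 20% of the mean — a conventional spread assumption, flagged in the
fixture because no source value is available. Independence is used because
no correlation structure is documented. The base analysis runs 10,000
iterations (Monte-Carlo SE of a proportion ≤ 0.5%) under a single seed, so
results are bit-reproducible; the cost-effectiveness acceptability curve
reports, per willingness-to-pay threshold $\lambda$, the fraction of draws
with net monetary benefit $\lambda\,\Delta\mathrm{QALY} - \Delta C \ge 0$.

```{r psa}
spec <- cfg$psa[names(cfg$psa) != "n_iterations"]
draws <- psa(cfg$static, spec, n = 10000, seed = 1)
prob_cost_effective(draws, cfg$meta$threshold)
```

## Validation and what the tests show

The test suite validates the engines three ways:

* **Closed-form special cases.** Geometric decay under constant resolution,
  the product-of-survival closed form under mortality alone, zero-hazard
  identity transitions.
* **Cross-model convergence.** With an 8-week horizon, no mortality,
  resolution or deterioration, and weekly AP hazards calibrated so each
  arm's expected episode count equals the static model's risk, the dynamic
  model reproduces the static QALYs and costs within 1%. The calibration
  targets expected episodes rather than first-episode probability because
  the static cost equation prices episodes; the Markov structure lets
  tunnel survivors relapse, and that repeat-episode mass (about 3% of the
  comparator's episodes) is a genuine structural difference between the two
  models, itself covered by a renewal-recursion test.
* **Property tests** over randomized valid configurations: row
  stochasticity and occupancy conservation, monotone death column,
  calibration/simulation round-trip identity on anchors, CEAC monotonicity
  and bounds.

The synthetic generators emulate the *statistical structure* the estimation
stage assumes — binomial 2×2 cohorts at stated risks and prevalence decay
induced by a weekly resolution schedule. They do not emulate patient-level
heterogeneity, correlated risks, time-varying consumption, or reporting
artefacts of real cohort studies, so passing tests demonstrate internal
correctness and calibration identities, not external validity of the
clinical inputs.

## Problem sizes and numerical choices

The shipped analyses use 52 weekly cycles, 10,000 PSA iterations for
headline probabilities (2,000 where only curve shape is checked), and
$10^6$ draws for distribution-moment checks. Transition rows are validated
to $10^{-9}$; round-trip identities to $10^{-10}$. Degenerate inputs are
handled explicitly: cumulative risk ≥ 1 and empty study lists are errors, a
zero incremental QALY yields an undefined-ICUR flag rather than division, a
zero-events reference group makes the relative risk undefined while a
zero-events exposed group returns a point of 0 flagged unreliable, and
horizons shorter than the mortality schedule's three segments truncate with
a warning.

## Limitations

The cohort is a hypothetical average patient: no age/sex subgroups, no
memory beyond the 2-week tunnel, no patient-level simulation. Thickener
consumption is constant over time although real patients likely step down
viscosity as they improve (a conservative choice — it overstates
intervention cost). Whether comparator patients can spontaneously stop
aspirating is undocumented; the base case disallows it, which if anything
favours the comparator's utility position being stable rather than
improving. Dynamic-model absolute results depend on the flagged placeholder
inputs described above and should be read qualitatively until supplied with
source values.
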