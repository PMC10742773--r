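---
title: "Model structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
a Markov cohort decision model comparing front-line ibrutinib plus RCHOP
(I-RCHOP) against RCHOP alone in patients 60 years of age or younger
with ABC-subtype diffuse large B-cell lymphoma, costed from a Canadian
public-payer perspective in 2022 CAD.

## State structure and clocks

The cohort occupies nine states: `front_line` (2 cycles of 3 months,
approximating six 21-day chemotherapy cycles), `disease_free`,
`salvage_gdp` (gemcitabine/dexamethasone/cisplatin), `auto_sct`,
`post_sct_disease_free`, `car_t`, `post_cart_disease_free`,
`palliative` (exactly 2 cycles — palliative care covers the last six
months of life) and `dead`. Patients relapsing from front-line treatment
or remission move to salvage; salvage responders proceed to autologous
SCT; non-responders receive CAR-T or palliation; relapse after SCT can
still lead to CAR-T, relapse after CAR-T only to palliation.

Two clocks drive hazards. Front-line EFS and OS Weibull curves run on
*model time* (they were fitted to trajectories from diagnosis). Salvage,
SCT, CAR-T and both post-remission relapse curves run on *time in state*,
because each was fitted to a trajectory starting at that state's entry.
Time-in-state is tracked exactly by internal tunnel expansion; the
returned trace aggregates back to the nine states.

## Transition probabilities

All survival inputs are rate-form Weibulls, S(t) = exp(-λ·t^k),
converted to conditional per-cycle probabilities
1 − S(t+Δ)/S(t). The rate form was chosen over the scale form
exp(−(t/λ)^k) because the published λ values (e.g. 0.016 for I-RCHOP
overall survival) would otherwise imply implausibly short survival. The
time unit of the published (λ, k) pairs is not stated in the source
analysis; the package defaults to **years** (configurable per row in the
parameter table). This is a documented reading, not an assertion of the
original authors' intent: of the three candidate units (years, months,
cycles), years produces the slowest and therefore most plausible event
accrual, yet even then the I-RCHOP EFS curve (λ = 0.181, k = 1.350)
falls to 0.20 by five years versus 0.46 for RCHOP (λ = 0.187,
k = 0.884). The consequences are discussed under *Known limitations*.

Within front-line and disease-free states, the per-cycle EFS event
probability is split so that death matches the OS curve and the
remainder is relapse (clamped at zero if OS events exceed EFS events in
a cycle). After five years of remission (20 cycles) the relapse hazard
is set to zero — the relapse plateau — on the model clock for front-line
remission and on the state clock for post-SCT/post-CAR-T remission.

Point probabilities are rescaled to the cycle grid by constant-rate
conversion, p_cycle = 1 − (1 − p)^(Δ/period). The published
adverse-event probabilities (0.642 I-RCHOP, 0.303 RCHOP) are modelled as
a **one-time per-course event** applying a cost and a one-cycle utility
decrement during front-line treatment, not as a separate health state;
the one-way sensitivity analysis treats the associated cost and
disutility as scalar parameters, which matches how they are interrogated
in the source analysis. The published annual post-CAR-T remission death
probability (0.059) is likewise rate-converted to the cycle grid.

Salvage non-responders split each cycle using the published weights
0.201 (to CAR-T) and 0.393 (to palliation) with the residual 0.406
remaining in salvage with persistent disease; the source does not state
the exact branching weights among these destinations, so this
renormalization is configuration, not asserted intent. Relapse after SCT
uses the same two weights renormalized to sum to one, since those
patients leave the SCT pathway.

## Background mortality

Every alive state is exposed to background mortality from a parametric
Gompertz–Makeham life table, h(a) = c + b·exp(g·a), with defaults
(c = 4e-4, b = 2e-5, g = 0.085) chosen so that 30-year survival of a
healthy 55-year-old is about 74% — a rough general-population magnitude
used as a stand-in, not official statistics. Background and
disease-specific hazards combine additively (competing exponential
risks), which the test suite checks against a 10^6-draw Monte-Carlo
competing-risk simulation. The hazard is stepwise-constant within each
year of age, so table survival equals the product of annual survival
probabilities exactly.

## Rewards, discounting, and incremental analysis

Life-years, QALYs and costs accumulate per cycle with a half-cycle
correction (occupancy averaged between consecutive cycle starts; on by
default, configurable). Discounting is per-cycle compounding of a 1.5%
annual rate, (1+r)^(−t), applied from the cycle's start time; one-time
costs (SCT, CAR-T, adverse events) are booked and discounted at the
cycle of state entry. Utilities live on the 0 (death) to 1 (perfect
health) scale, so QALY ≤ LY holds by construction.

`compute_icer()` sorts strategies by cost, removes strictly dominated
strategies, applies extended dominance along the frontier, and reports
ICERs between frontier neighbours. Extended dominance is implemented
even though the analysis has only two strategies, to keep the engine
reusable; a brute-force least-ICER frontier construction serves as the
test oracle. When the intervention adds no QALYs, pairwise contrasts are
labelled dominated rather than given an ICER.

## Synthetic economic tables and calibration

The per-state cost and utility tables behind the source analysis are not
publicly printed, so `make_econ_tables()` draws them reproducibly from
documented plausible 2022-CAD ranges: e.g. CAR-T one-time cost 380–480k
far above auto-SCT (80–120k), ibrutinib adding 22–30k per 3-month
front-line cycle, remission utilities around 0.74–0.90 and palliative
utility lowest (0.30–0.42). Every file written from them carries a
SYNTHETIC stamp. The ranges are the package's own choices of what a
Canadian health economist would call plausible; they are not published
unit costs.

`calibrate_to_targets()` adjusts utilities and costs so the
deterministic model reproduces target per-strategy totals. Because the
cohort trace does not depend on the economic tables, the totals are
exactly linear in the free parameters; the bounded least-squares search
re-accumulates rewards over precomputed traces, with a small ridge
penalty keeping the solution near the starting tables. A handful of
totals cannot identify ~20 free parameters, so recovered tables are one
feasible solution among many — outputs, not parameters, are asserted,
and the parameter-recovery test in the suite checks exactly that. A QALY
target above its LY target is rejected outright; a QALY target above the
model's achievable discounted life-year ceiling is reported loudly via
the achieved residuals and a warning, never silently absorbed.

## Probabilistic and deterministic sensitivity analysis

The PSA uses conventional families moment-matched from (mean, SE): beta
for probabilities, utilities and disutilities; gamma for costs;
lognormal for Weibull λ and k. The source analysis publishes SDs only
for outcomes, not inputs, so input SEs default to 10% of the mean — a
documented stand-in consistent with the ±10% one-way interrogation. The
automatic SE is capped at a beta-feasible value for utilities near 1.
Parameters are drawn independently (no published correlation structure);
both arms are evaluated on the same joint draw (common random numbers),
pairing the contrast and reducing Monte-Carlo variance of the ICER.
Because independently drawn branch probabilities can sum past one, the
two constrained pairs (SCT outcomes; CAR-T/palliation weights) are
rescaled onto the simplex within a draw when needed. The acceptability
curve assigns each draw to the strategy with maximal net monetary
benefit, splitting exact ties equally.

The one-way analysis perturbs one parameter at a time by ±10% on its
natural scale, clamped to its domain (probabilities and utilities to
[0, 1], costs to non-negative) — probability-scale perturbation, not
odds-scale, matching the plain "by 10%" phrasing. Entries record both
bound ICERs; the tornado orders by descending range with an alphabetical
tie-break, and `threshold_check()` flags any bound crossing the
willingness-to-pay threshold.

## Numerical choices

Cycle conversion and telescoping are exact: the product of per-cycle
survival probabilities reproduces the Weibull survival function at every
cycle boundary to 1e-10, and a unit shape parameter reduces to the
exponential closed form. Survival underflow in deep tails returns a
per-cycle probability of 1 with a warning. Row-stochasticity of every
resolved transition matrix is asserted to 1e-12 and cohort mass
conservation to 1e-9 across randomized configurations. All randomness
flows through explicit seeds; PSA runs are byte-identical under a fixed
seed. Problem sizes used by the test suite — 500 randomized engine
configurations, 10^6 competing-risk draws, 10^5 toy-model PSA draws,
200-draw full-model acceptability curves — were chosen to make
Monte-Carlo assertions decisive at 3 standard errors while keeping the
default suite quick to run.

## Known limitations

* **The published Weibull parameters contradict the published
  direction.** Under every available reading of the printed (λ, k)
  pairs, I-RCHOP's EFS curve accrues events faster than RCHOP's beyond
  the first year, sending roughly three quarters of the I-RCHOP cohort
  through the salvage pathway within five years. The salvage pathway is
  costly and deadly (most non-responders reach palliation), so the
  model's I-RCHOP arm accrues *fewer* discounted life-years than RCHOP
  and is strictly dominated — the opposite of the published headline, in
  which I-RCHOP gains 1.23 QALYs at an ICER of ~34,000 CAD/QALY. For the
  same reason the published QALY totals (15.479 / 14.245) exceed the
  discounted life-year ceilings this structure can reach, and
  calibration reports residuals of roughly −27% to −36% on QALYs while
  matching the cost totals essentially exactly. The package reports
  these tensions quantitatively rather than resolving them by
  reparameterization.
* Branching weights for salvage non-responders, the time unit of the
  Weibull parameters, the front-line treatment duration (2 cycles), the
  starting age (55, midpoint of an under-60 adult cohort) and the
  half-cycle correction are configuration with documented defaults, not
  published facts.
* The synthetic generator emulates magnitudes and orderings of Canadian
  costs and utilities, not their joint empirical distribution; passing
  tests demonstrate internal consistency of the engine and analyses, not
  agreement with unpublished appendix data.
* Microsimulation features (individual heterogeneity, explicit GDP cycle
  counts, stem-cell logistics) and value-of-information analyses are out
  of scope.
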