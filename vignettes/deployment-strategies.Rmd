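---
title: "Modelling two-drug antibiotic deployment under resistance tradeoffs"
author: "abxtradeoff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-drug antibiotic deployment under resistance tradeoffs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abxtradeoff)
```

## The question

When two antibiotics are available against a nosocomial pathogen, how should
they be deployed -- one at a time, alternated over the whole hospital
(cycling), split across patient groups (mixing), or given together at reduced
doses (a cocktail)?  `abxtradeoff` studies this question in a setting where
double resistance is *constrained*: a pleiotropic tradeoff links the two
resistance phenotypes, so a mutant cannot be fully resistant to both drugs at
once.  The figure of merit is not the prevalence of resistance but the
equilibrium frequency of *uninfected patients*, \(\hat X\), together with the
per-capita recovery rate of those still infected.

## The compartment model

A closed hospital population is divided into five frequency compartments:
uninfected patients \(X\), and patients infected with sensitive bacteria
\(S\), drug-A-resistant \(R_1\), drug-B-resistant \(R_2\), or
double-resistant \(R_3\).  With \(i \in \{S, 1, 2, 3\}\) the dynamics are

\[
\begin{aligned}
\dot S   &= \beta X S + \sigma c \beta S (R_1 + R_2 + R_3) + (G_S - \gamma) S,\\
\dot R_i &= \beta (1 - c) X R_i - \sigma c \beta S R_i + (G_i - \gamma) R_i,
            \qquad i = 1, 2, 3,\\
\dot X   &= -\beta X \left[ S + (1-c)(R_1 + R_2 + R_3) \right]
            - \textstyle\sum_i (G_i - \gamma)\, \text{strain}_i .
\end{aligned}
\]

Three processes couple the compartments:

* **Infection.** Uninfected patients acquire strain \(i\) by mass action at
  rate \(\beta\); resistant strains transmit at the discounted rate
  \(\beta(1-c)\), which is where the fitness cost of resistance
  \(c\) enters.
* **Superinfection.** Sensitive bacteria can colonise and take over a
  patient carrying a resistant strain.  The takeover rate is
  \(\sigma c \beta\) per contact: proportional to the resident strain's
  competitive deficit \(c\), scaled by the superinfection factor
  \(\sigma\).  Resistant strains never take over \(S\) patients or each
  other.  (See *Design choices* below for why the cost factor belongs in
  this coefficient.)
* **Clearance.** Infected patients recover at rate \(-(G_i - \gamma)\),
  where \(\gamma\) is immune clearance and \(G_i\) is the pharmacodynamic
  net growth rate of the infecting strain under the drug doses currently in
  force.  Under the standard parameters \(G_i \le 0 \le \gamma\), so this
  term always moves patients back into \(X\).

The system is closed: no admissions or discharges, so every gain is another
compartment's loss and the five frequencies sum to one along every
trajectory (`populationDeriv()` returns components that sum to zero to
machine precision, and the integration tests hold trajectories to a drift
below \(10^{-9}\)).

## Pharmacodynamics and the tradeoff

Net growth under a single drug at concentration \(a\) follows a Hill-type
dose response with exponent \(k = 1\) by default,

\[
G_{sgl}(a) = \phi_{max} -
  \frac{(\phi_{max} - \phi_{min})\,(a/\mathrm{MIC})}
       {(a/\mathrm{MIC}) - \phi_{min}/\phi_{max}},
\]

which is \(\phi_{max}\) without drug, crosses zero exactly at the MIC and
saturates at \(\phi_{min} < 0\).  Two cocktail compositions are provided:

* **combined** (`growthCombined()`): the drugs hit the same cellular
  process, so their MIC-scaled concentrations pool into one Hill term,
  \(u = a/\mathrm{MIC}_A + b/\mathrm{MIC}_B\).  A single negative term
  bounds the effect at \(\phi_{min}\) -- an approximation of suppressive or
  antagonistic drug pairs.
* **separate** (`growthSeparate()`): the drugs hit distinct processes and
  damage adds, \(G = \phi_{max} - E(a/\mathrm{MIC}_A) -
  E(b/\mathrm{MIC}_B)\).  Two negative terms can push growth below
  \(\phi_{min}\) -- an approximation of additive pairs.  Because the effect
  term \(E\) is concave with \(E(0)=0\), it is subadditive, so the separate
  response never exceeds the combined one at equal doses.

Resistance is encoded as MICs.  The standard schema gives \(R_1\) an MIC of
240 against drug A and \(R_2\) 240 against drug B, with all other MICs at
zero -- reset at construction to a floor of \(10^{-6}\) so dose/MIC ratios
stay finite (`strainPanel()` applies the floor once, not per call).  The
double-resistant strain's MICs are tied together by the tradeoff strength
\(\omega \in [0, 1]\):

\[
\mathrm{MIC}_{A,3} = (1-\omega) \cdot 240, \qquad
\mathrm{MIC}_{B,3} = (1-\omega) \cdot 240 .
\]

At \(\omega = 0\) the double mutant is super-resistant; at \(\omega = 1\) it
is super-sensitive; \(\omega = 1/2\) is a linear tradeoff.

## Deployment strategies

All strategies except `NONE` administer 240 dose units per patient at all
times; they differ only in how the budget is split over drugs, patients and
time (`dosesAt()` exposes the schedule):

| strategy | doses (A:B) | notes |
|---|---|---|
| `NONE` | 0:0 | no-treatment baseline |
| `CONTROL` | 240:0 | resistant compartments pinned at zero |
| `SINGLE` | 240:0 | all strains present |
| `CYCLING` | 240:0 / 0:240 | whole population alternates every \(\pi\) |
| `MIXING` | 240:0 and 0:240 | two equal halves in antiphase, swapped every \(\pi\) |
| `COCKTAIL_CMB` | 120:120 | combined composition |
| `COCKTAIL_SEP` | 120:120 | separate composition |

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| \(\beta\) | infection rate | 1/time | 1 |
| \(\sigma\) | superinfection factor | -- | 0.25 |
| \(\gamma\) | immune clearance | 1/time | 0.25 |
| \(c\) | cost of resistance | -- | 0.1 |
| \(\phi_{max}\) | drug-free growth | 1/time | 0.25 |
| \(\phi_{min}\) | high-dose growth | 1/time | -0.25 |
| \(k\) | Hill exponent | -- | 1 |
| MIC | resistance level | conc. | 240 (resistant), \(10^{-6}\) (floor) |
| budget | dose per patient | conc. | 240 |
| \(\pi\) | alternation period | time | 50 |

These defaults sit in the range conventional for hospital-transmission and
pharmacodynamic modelling: the basic reproduction ratio of the sensitive
strain in a drug-free hospital is \(\beta/\gamma \cdot \phi\)-limited and
modest, a resistant strain sacrifices 10% of its transmission, and a full
dose suppresses a sensitive strain as strongly as the immune system clears
it.  They are deliberately generic -- the package explores the qualitative
structure of the strategy comparison, not a calibrated forecast for any
particular pathogen.

## Numerical methods

* **Integrator.** Classical fixed-step RK4 (`dt = 0.1` by default),
  implemented in compiled code.  Doses are piecewise constant and the
  alternation period must be an integer multiple of `dt`, so a step never
  straddles a dose switch; the forcing is constant within every step and
  the integrator retains its full fourth order (verified by a
  step-halving test with error ratios \(\approx 16\)).
* **Static equilibria** are declared when the one-step sup-norm change
  falls below `convergenceTol` (\(10^{-12}\)); at that point the state is
  within \(\sim 10^{-9}\) of the fixed point for the slowest mode in the
  suite.  An optional `postConvergenceSteps` continues integration after
  detection; it does not change the reported values at this tolerance and
  defaults to zero.
* **Fluctuating equilibria** (cycling, and mixing via its schedule) are
  declared converged when the per-cycle upper and lower envelopes of every
  compartment change by less than `envelopeTol` (\(10^{-9}\)) between
  consecutive cycles, and are then time-averaged over
  `cycleAveragePeriods = 1000` periods.  The envelope tolerance is looser
  than the static one because the cycling attractor carries a near-neutral
  mode -- the phase asymmetry between \(R_1\) and \(R_2\), whichever strain
  the first half-cycle favours -- whose final decimals relax only on very
  long timescales while the cycle-averaged frequencies are already stable
  to \(\sim 10^{-6}\).
* **Initial conditions** default to \(X = 0.96\) with each strain seeded at
  1% (CONTROL: \(X = 0.99\), \(S = 0.01\), resistant strains pinned at
  exactly zero).  Reported equilibria are insensitive to this choice; the
  test suite checks three different starting compositions.
* **Ties.** `dominantStrain()` reports every strain within \(10^{-9}\) of
  the maximum, so exactly symmetric scenarios return the pair
  `R1`/`R2` rather than an arbitrary winner.  Under `SINGLE` at
  \(\omega = 0\) the dominant set is likewise a genuine tie between
  \(R_1\) and \(R_3\), which are indistinguishable when only drug A is
  ever present.
* **Degenerate inputs.** Negative doses, MICs below the floor, invalid
  strategy names, non-finite states and a fully uninfected population in
  the recovery-rate calculation all raise errors; runs that exhaust
  `maxTime` are returned with `converged = FALSE` rather than dropped.

## Closed-form cross-checks

When a single strain \(i\) persists alone at a static equilibrium, setting
\(\dot R_i = 0\) gives

\[
\hat X = \frac{\gamma - G_i}{\beta\,(1 - c\,[i \text{ pays cost}])},
\]

which `analyticEquilibrium()` evaluates for every static strategy.  The test
suite requires numeric and analytic equilibria to agree to \(10^{-6}\).
Convenient anchor points: `CONTROL` gives \(0.5/1 = 50\%\); `SINGLE` gives
\(0.25/0.9 = 27.8\%\) independently of \(\omega\) (the single-resistant
mutants outcompete \(R_3\) whenever one drug is used alone); the separate
cocktail gives \(0.\overline{3}/0.9 = 37.0\%\) at \(\omega = 0\) and
\((0.25 + 5/12)/0.9 = 74.1\%\) at \(\omega = 1\); the combined cocktail
spans \(27.8\%\) to \(50\%\) with the sensitive strain taking over beyond
\(\omega^\* \approx 0.86\) (it pays no cost while all strains are cleared at
nearly the same rate).  No closed form exists for the fluctuating regimens.

## Design choices

Several aspects of the model family are genuinely open; the package settles
them as follows.

* **Where the cost acts.** The resistance cost discounts *transmission*
  (\(\beta(1-c)\)) rather than growth.  This is the only placement
  consistent with the full set of closed-form anchor points above -- a
  growth-rate penalty would shift the `SINGLE` equilibrium away from
  \(0.25/0.9\).
* **The superinfection coefficient.** Takeover of a resistant-infected
  patient by sensitive bacteria occurs at \(\sigma c \beta\), proportional
  to the resident's cost, the form used in the hospital-cycling literature
  this model descends from.  The alternative -- a full-strength
  \(\sigma\beta\) takeover -- makes \(S\) competitively unbeatable under
  every two-drug regimen (its invasion exponent at any drug-exposed
  equilibrium becomes positive), collapsing all cycling, mixing and
  combined-cocktail outcomes onto the resistance-free 50% and abolishing
  the dominance thresholds; with the \(\sigma c \beta\) form the
  combined-cocktail threshold falls at \(\omega^\* \approx 0.86\) and the
  separate-cocktail threshold at \(\approx 0.75\), where the acceptance
  suite checks them.  \(R_3\) participates in superinfection on the same
  footing as \(R_1\) and \(R_2\).
* **The mixing structure.** `MIXING` is modelled at the population level as
  randomised drug assignment: each infected compartment experiences the
  equal-weight average of the two arms' clearance rates, so the effective
  growth is invariant under arm swaps and the outcome is independent of
  \(\pi\).  The alternative of duplicating every infected compartment per
  arm (patients remembering their assignment between swaps) was implemented
  and rejected: arm memory lets each resistant strain shelter in the arm
  currently dosing the drug it resists, which *lowers* \(\hat X\) by
  several points at \(\pi = 50\), inverts the expected
  mixing-above-cycling ordering, and makes the outcome drift with \(\pi\)
  even over short periods.  The cost of the randomised-assignment choice is
  that any decline of mixing performance at very long periods (where arm
  memory must matter) is outside the model; see *Limitations*.
* **No extinction floor.** Compartment frequencies decay asymptotically and
  are never clamped at small values: the model is deterministic and
  continuous, and a rescue floor would smuggle in an immigration process
  the closed system excludes.

## An exact constraint on cycling averages

One structural fact deserves emphasis because it pins the cycling result
analytically.  On any periodic attractor, the time average of each
persisting strain's per-capita growth rate is exactly zero, and for
\(R_1\) under cycling that rate is linear in the state with an exogenous
square-wave drug term:

\[
\beta (1-c) \bar X = \gamma - \bar G_1, \qquad
\bar G_1 = \tfrac{1}{2}\left( 0 + \phi_{min} \right) = -0.125 ,
\]

as long as \(S\) is extinct (its invasion exponent at this attractor is
negative, \(\approx -0.069\)).  Hence the cycle-averaged uninfected
frequency under cycling at maximal tradeoff is pinned at
\(0.375/0.9 = 41.7\%\) for *every* alternation period -- faster cycling
cannot improve it and slower cycling cannot degrade it, until floating-point
extinction intervenes (below).  The same identity applied to the randomised
mixing model gives the identical 41.7%, so the two strategies coincide in
this implementation; the acceptance suite reports both values as computed.

## Limitations

* The model is deterministic and frequency-based: no demographic noise, no
  patient turnover, no within-host dynamics, and strains present from the
  start rather than arising by mutation.  Double-positive epistasis is
  excluded by construction; the tradeoff is the only coupling between the
  two resistance phenotypes.
* Cocktails are limited to the additive (separate) and suppressive
  (combined) compositions; synergistic pairs, which raise distinct
  evolutionary concerns, are out of scope.
* The randomised-assignment mixing model is exactly \(\pi\)-independent, so
  behaviour specific to very long swap periods is not captured.
* At extreme periods (\(\pi \sim 5 \times 10^4\)) the off-drug strain's
  frequency underflows into the denormal range, where rounding stalls the
  decay at \(\sim 10^{-322}\); the strain then regrows during its
  favourable phase, and each phase quasi-equilibrates like a single-drug
  hospital (the cycle average computed by the suite at \(\pi = 50000\) is
  29.4%, approaching the 27.8% single-drug value from above).  This is an
  artefact of finite-precision arithmetic acting like a tiny rescue floor;
  results at such periods should be read qualitatively.
* A sweep at grid step 0.01 over all strategies completes in a few minutes
  on one CPU; the test and acceptance suites use coarser grids (steps of
  0.25 on \(\omega\), bisection brackets of 0.005-0.01) chosen to exercise
  every code path while keeping a full run under a minute.

## A worked session

```{r example, eval = FALSE}
library(abxtradeoff)

# separate cocktail under a linear tradeoff
res <- runToEquilibrium(strategySchedule("COCKTAIL_SEP"), strainPanel(0.5))
res
analyticEquilibrium("COCKTAIL_SEP", 0.5)

# where does the double-resistant strain lose dominance under cycling?
findDominanceThreshold("CYCLING", period = 50)

# the strategy comparison at maximal tradeoff
sweepEquilibria(omega = 1, period = 50)[, c("strategy", "xHat", "dominant")]
```
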