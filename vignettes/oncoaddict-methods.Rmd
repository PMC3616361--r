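---
title: "Modeling oncogene addiction: the six-state simulator and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling oncogene addiction: the six-state simulator and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoaddict)
library(dplyr)
library(ggplot2)
```

## The biological problem

Tumors driven by the overexpression of a single oncogene can be "addicted"
to it: switching the oncogene off — experimentally, via a
tetracycline-controlled MYC transgene and doxycycline in the drinking
water — triggers a coordinated collapse of the tumor. The collapse is not
one process but several: proliferative arrest is almost immediate,
apoptosis follows after a delay of several days, some cells differentiate
into an apparently normal (but potentially dormant) state, and, when the
host immune system is intact, others enter irreversible oncogene
inactivation-induced senescence (OIIS). In immunocompromised hosts the
senescence program fails, residual MYC-off cells persist longer, and rare
cells escape conditional control altogether (through mutations in the
tetracycline machinery or activation of downstream pathways), seeding
relapse. Bioluminescence imaging (BLI) of conditional mouse models shows a
characteristic signature: regression curves from replicate animals overlap
almost perfectly, while relapse curves fan out in time.

`oncoaddict` implements a stochastic population model of this biology and
the analysis tooling around it: which features of the data force which
modeling ingredients (multiple cell states, stochastic transitions, an
explicit commitment-to-death delay), and what the model then predicts
about relapse kinetics.

## The model

### States and transitions

Each tumor cell occupies one of six states:

| state | meaning |
|---|---|
| `M` | MYC program active; proliferating |
| `N` | MYC switched off, still under tetracycline control |
| `A` | irreversibly committed to apoptosis, not yet dead (still imaged) |
| `D` | differentiated to a quasi-normal, possibly dormant state |
| `S` | senescent (OIIS); irreversible arrest, absorbing |
| `E` | escaped from conditional MYC control; proliferating |

Transitions are first-order with the rate constants of
`onco_params()` (all day^-1): `M` cells proliferate (`k_M_prolif = 0.5`)
and commit to apoptosis (`k_M_apop = 0.05`); `N` cells proliferate weakly
(`k_N_prolif = 0.1`), commit to apoptosis quickly (`k_N_apop = 2`),
differentiate (`k_diff = 0.02`), senesce (`k_senesc = 0.001`) or escape
(`k_relapse`); `D` cells die slowly (`k_D_apop`, tumor-type dependent:
0.05 lymphoma, 0.002 osteosarcoma, 0.01 hepatocellular carcinoma) or
reawaken to `M` (`k_wake = 0.1`); `E` cells proliferate (`k_E_prolif =
0.5`) and die (`k_E_apop = 0.01`).

Three gates encode the experimental control and the host context:

* **The doxycycline switch.** `M -> N` (rate `k_inactivation = 2`) is open
  only while the MYC program is off; `N -> M` (`k_activation = 2`) only
  while it is on. The path is open in one direction at a time, and because
  the rates are finite the M/N interconversion is non-instantaneous
  (pharmacokinetics are otherwise not modeled: the program is a binary
  schedule, `myc_schedule()`).
* **Immune status.** Escape is immune-gated: `k_relapse = 0` in competent
  hosts, `3e-8` in deficient hosts. We additionally set `k_senesc = 0` in
  deficient hosts, since OIIS requires host CD4+ T cells; the parameter
  table we inherit marks only `k_relapse` as immune-split, so this extra
  gating is an interpretive choice of this package — it is documented
  here, and overridable (`onco_params("lymphoma", "deficient", k_senesc =
  0.001)`).
* **Dormancy reawakening.** `D -> M` is open only while the MYC program is
  on: dormant differentiated cells regain the neoplastic state upon MYC
  reactivation, not spontaneously.

Proliferation is a *birth event*, not a state exit: the mother remains in
her state and one daughter is added to it. No explicit mitotic
compartment or age structure is carried; daughters become eligible for
transitions at the next step.

### Time stepping and the stochastic update

Both engines advance on a fixed Euler grid with `dt = 0.02` days, small
relative to the fastest rate (2/day). Per step, each open edge carries
probability `p = K * dt` (first order, matching the Euler scheme; at this
`dt` the difference from `1 - exp(-K dt)` is at most 2% of the per-step
probability for the fastest rate and far less for the others). The
stochastic engine draws, for each source state with `n` cells, a single
multinomial over its open exits plus "stay", so exits are mutually
exclusive and can never move more cells than exist; births are binomial.
The exact multinomial is kept rather than the independent-binomial
approximation that the low per-step probabilities would justify. Above
the 32-bit size limit of R's `rmultinom()` the draw is factored into the
exact chain of conditional binomials, so nothing changes statistically
for very large populations.

The deterministic engine replaces every draw by its mean `n * p`. Because
both engines share the same kernel, grid and delay bookkeeping, the
deterministic trajectory is the *exact* expectation of the stochastic
one — which is what the mean-field convergence tests assert (averages of
replicate runs, not closed-form exponentials, are the correct oracle for
the stochastic engine; the discrete scheme itself deviates from the
continuous exponential by the usual first-order bias, about `t K^2 dt/2`
in log-scale, i.e. 2% after 10 days of growth at net rate 0.45/day).

### The commitment-to-death delay

Cells that commit to apoptosis keep producing BLI signal until they
actually die. Without representing this, simulated regression begins
immediately at inactivation, which contradicts the imaging: arrest is
immediate but shrinkage lags by 4–5 days. The model therefore treats `A`
as a delay line: a cohort committing during the step starting at `t` is
enqueued with death time `t + tau_apop` and removed during the step whose
end first reaches that time (a FIFO cohort queue in the stochastic
engine, `delay_queue()`; the equivalent flux-history form `dA/dt =
influx(t) - influx(t - tau_apop)` in the deterministic engine). The
pre-history of commitments before `t = 0` is zero. `tau_apop` must sit on
the grid and is rounded there with a warning.

No printed value exists for `tau_apop`; it is a calibration constrained
by the observed 4–5 day lag. The default is 4.5 days, and with it the
deterministic lymphoma scenario shows an emergent onset of decline of
5.0 days after inactivation — at the edge of the observed window, because
the population keeps growing (residual `M` proliferation plus delayed
deaths) for a while after the switch, so the measured onset trails
`tau_apop` itself. `onset_of_decline()` defines the onset operationally
as the first persistent (default 1 day) drop below 99% of the signal at
the switch.

### Default study conditions

The figures in the source experiments do not publish axis scales or
initial tumor sizes, so the package fixes a single realistic default: 1e6
MYC-on cells at `t = 0`, ten days of growth (reaching about 9e7 cells),
then inactivation. The scenario presets build on it:

* `fig4` — immunocompetent, `tau_apop = 0` (delay ablation), 40 days;
* `fig5` — immunocompetent, `tau_apop = 4.5`, 40 days;
* `fig6` — immunodeficient single run, 80 days;
* `fig7` — immunodeficient, 20 replicates, 80 days.

The 80-day horizon covers the median relapse (~46 days) plus its spread.
With ~9e7 cells passing through `N` at a residence time of ~0.5 days, the
expected number of escape events per run at `k_relapse = 3e-8` is of
order one — exactly the regime where relapse occurrence and timing are
stochastic, and the reason a deterministic treatment of escape misses the
observed variability.

## Summary metrics

* `onset_of_decline()` — persistent 1%-drop detector described above.
* `regression_half_time()` — days from inactivation to half the
  at-switch signal. The source experiments never define a numeric
  regression statistic; this operational choice is ours.
* `relapse_time()` — first re-crossing, after the post-inactivation
  nadir, of a threshold fraction (default 50%) of the pre-inactivation
  peak; requires the signal to have regressed below the threshold first.
  The threshold is configurable and reported with results.
* `variability_report()` — coefficients of variation of the half-time and
  the relapse time across an ensemble, computed over the runs where each
  is defined. No quantitative target exists for "little" versus "greater"
  variability; only the inequality `cv_relapse > cv_regression` is
  asserted.
* `relapse_rate_sensitivity()` — grid sweep over `k_relapse` and
  `k_E_prolif` reporting the median relapse time per cell.

## A worked comparison

```{r delay, fig.width = 6.5, fig.height = 4}
with_delay <- run_scenario("fig5", deterministic = TRUE)
no_delay <- run_scenario("fig4", deterministic = TRUE)
c(
  onset_with_delay = onset_of_decline(with_delay),
  onset_no_delay = onset_of_decline(no_delay)
)
autoplot(with_delay, states = FALSE)
```

```{r ensemble, fig.width = 6.5, fig.height = 4}
ens <- run_scenario("fig7", seed = 11)
glance(ens)
autoplot(ens)
```

The regression limbs of the twenty runs coincide (the half-times are
identical to grid resolution, CV about 0), while relapse times spread over
roughly a week — the variability asymmetry the stochastic formulation
exists to capture.

## Numerical choices

* **Fixed-step Euler, no adaptivity.** The fixed grid at `dt = 0.02` is
  part of the model specification being reproduced, not a numerical
  convenience; the stochastic update is defined per grid step. No
  event-driven (Gillespie) formulation is provided.
* **Verification oracles.** `oracle_fine_grid()` integrates the same
  system at `dt / refinement` for convergence checks. For zero-delay
  constant-program regimes the model is a linear ODE, and the test suite
  compares the refined integrator against `Matrix::expm()` (agreement
  ~0.002% at refinement 100 over 10 days; the production grid itself sits
  within the expected first-order error of the continuous system — 0.2%
  for slow-mode regimes, ~2% for a 10-day growth phase).
* **Determinism.** Each stochastic run uses one seeded RNG stream
  (`withr::with_seed`); ensembles spawn per-run seeds by a single seeded
  `sample.int()` over the 31-bit range from the base seed, so results are
  reproducible bit-exactly and independent of replicate order. Output CSVs
  are written at full (shortest round-trip) precision so replays are
  byte-identical.
* **Degenerate inputs.** Empty states skip their draws; zero-rate models
  are exact no-ops; negative expected counts cannot arise from the update
  itself (outflow probabilities sum to at most 1, enforced at
  construction and again per run), and the engine clamps-and-warns as a
  guard only.
* **Probability bound.** Any parameter/`dt` combination whose worst-case
  per-step exit probability exceeds 1 for some state is rejected at
  construction with a message naming the remedy (smaller `dt`).

## What the simulations do and do not show

The synthetic scenarios emulate the *kinetic skeleton* of the
experiments: timing of arrest, delayed death, differentiation and
senescence fluxes, and rare-escape relapse. They do not emulate
measurement noise of BLI, pharmacokinetic ramping of doxycycline,
angiogenesis and its inhibition, explicit immune effector populations
(immunity enters only through rate gating), tumor stem-cell heterogeneity
or spatial structure. Passing tests therefore demonstrate internal
consistency of the model and agreement with the qualitative/semi-
quantitative anchors above — not quantitative fit to any particular
animal's imaging series. The BLI proxy defaults to *all* live states
(including `D` and `S`); whether differentiated or senescent cells should
contribute signal is genuinely unsettled, so the set is configurable
(`bli_states`).

## Known limitations

* `tau_apop` is a single deterministic lag; real commitment-to-death
  times are dispersed. A distributed delay would smooth the onset.
* Escape is a single lumped first-order event; mechanistic routes (tTA
  mutation, Notch/MAPK/Wnt activation) are not distinguished.
* The model is linear in cell counts: no carrying capacity, no
  immune-load saturation, no tumor-size feedback on regression. The
  deterministic engine's linearity is exploited by the test suite
  (trajectory scaling) and is also a modeling limitation.
* Problem sizes in the test suite (ensembles of 20–200 runs, horizons of
  10–80 days, grids of 500–4000 steps) were chosen to exercise every
  regime of the model at interactive runtimes.
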