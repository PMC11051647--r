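---
title: "Model and methods behind glossim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind glossim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

glossim simulates the daily dynamics of a riverine tsetse population on a
lattice of 1-km cells and its suppression by insecticide-treated Tiny
Targets. This vignette records the model, its assumptions, the tunable
parameters, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite and the
acceptance script do not themselves compute.

## The landscape

Cells belong to one of four habitat classes — large river, medium river,
small river, interfluve — with good-habitat cover fractions 0.10, 0.07,
0.04 and 0.01 of the cell area and natural-mortality multipliers 1.00,
1.05, 1.10 and 1.20. Rivers are axis-aligned polylines (so that riverine
cells are orthogonally connected, which daily orthogonal movement
requires); a river's class follows its distance from the source: small for
the first 7 cells, medium for the next 21, large thereafter. At a
confluence the downstream cell takes the class implied by the longest
upstream path, which keeps the 7/28-cell rule well defined for any
tributary structure. Coordinates are 1-based `(row, col)` with row 1 at
the North edge — the natural convention for R matrices — and cell ids are
column-major indices.

The bundled `uganda_schematic()` landscape is a hand-authored
approximation of the study area the model was built around: a N–S
watershed near the western edge, rivers draining East, interfluves
typically two cells wide, five treated monitoring plots plus the untreated
`oluffe` (3 km from treated rivers on both sides) and `koboko` (far North,
separate river) plots, and a long "chosen" river crossing the map for
transects. The real river layout is not available as data, so per-cell
absolute results depend on this approximation while the qualitative
patterns (upstream/downstream contrast, invasion control, knock-on effects
beyond treated sections) do not.

## Demography

The state holds continuous-valued counts — the model is deterministic,
with no demographic stochasticity or integer rounding — of adult females
and males in daily age classes 1–100 and of pupae aged 1–30 by natal
cell. Defaults: first larviposition at adult age 16 days, one larva per
10 days thereafter, 30-day pupal period, pupal daily mortality 0.005 at
carrying capacity, zero egg/larval mortality. These are standard tsetse
lifecycle values; the exact age-specific profile used by the original
spreadsheet implementation is not published, so adult natural mortality is
flat across ages and solved (below). Printed per-cell equilibria
downstream of that choice reproduce closely for medium rivers and only
approximately for small rivers, which is why the test suite asserts the
former and not the latter.

Natural death rates are density dependent:
`m_d = m_s ((1 - k) + k d / s)` with `k = 0.1`, where `d` is the current
density per km² of habitat (cell count divided by cover — adults use total
males plus females, pupae total pupae) and `s` the density at the standard
natural carrying capacity, 5000 females + 2500 males per km² of best
habitat for adults. The pupal reference density is not a free input: it is
the equilibrium standing pupal density implied by the solved lifetable, so
that pupal rates equal their nominal value exactly at equilibrium.

`goal_seek_natural_mortality()` finds the flat adult rates by a bracketing
root search on the long-run daily growth rate of the female line
(Euler–Lotka condition, |growth| < 1e-8/day), then solves the male rate so
the standing male population is half the female one under the equal
recruitment of the sexes. Both rates are corrected for the engine's
within-day accounting — density is read after aging and before emergence —
so the simulated fixed point sits at the carrying capacity itself, not
merely the continuous-time one; the suite verifies a 2000-day run stays
within 0.1% of it. Survival factors are clamped to [0, 1].

Larviposition is smeared by default (rate `1/interlarval_period` for every
female at or beyond the age of first larviposition), which yields the
steady stream of emergence the model's equilibria assume; a synchronized
mode (each female deposits exactly on her schedule) is available via
`standard_config(demography = list(larviposition = "synchronized"))`.

## Movement

All adults at a cell centre move equally in the four orthogonal
directions; a fraction `p/4` per direction transfers to the neighbouring
centre and the rest return. The daily evacuation probability `p` is
calibrated per sex and age so that an unconstrained walk attains a mean
absolute displacement of `nominal * sqrt(30)` km after 30 days — the
diffusive reading of "average daily displacement", chosen because matching
a fixed daily step over a short horizon misstates long-run spread on a
1-km lattice, and the 30-day assessment horizon is the model's own remedy
for exactly that. The calibration inverts an exact convolution of the
step distribution (`mean_walk_displacement()`), verified against a
Monte-Carlo oracle in the tests. Nominal displacements: 0.2 km/day for
age-1 females rising linearly to 0.4 km/day at age 10 and constant after;
males half at every age.

Movement toward poorer habitat is damped: by the cover ratio between river
classes (e.g. 0.7 from large to medium), by 0.01 from a river into an
interfluve, and not at all toward equal or better habitat. Damped flies
are back at their origin centre the same day and experience that cell's
mortality and control. Map edges reflect, so movement conserves every
sex-age cohort exactly (the movement operator has zero column sums).

## Control

Kill rates are defined per target at a density of one target per km² of
habitat: the base schedule kills 0.01% of age-1 females per day, rising
linearly to 0.05% at age 10 and constant after; males are killed at 80% of
the female rate. Schedules are named by their old-female rate and scale
every sex- and age-specific rate proportionally (so Schedule 0.01 kills
0.002% of age-1 females — the whole profile scales, not just its
plateau). Deployment is 20 targets per treated riverine cell, i.e.
200/286/500 per km² of habitat for large/medium/small rivers. Daily kill
in a treated cell is `min(1, rate × density × efficacy)` — linear in
target density, since rates are defined per target at unit density, with
the cap guarding degenerate configurations. Efficacy declines by first
order (`(1 - degradation)^days`, standard 1.5%/day, ~6% left after six
months); at the start of the 184th day of each cycle the old targets are
discarded and a fresh set deployed, for as long as the plan runs.

## Simulation procedure

Each day executes: advance the date and age all compartments; natural
mortality; movement; control; larviposition; emergence. Mortality before
movement within step order is a documented choice (the original's
within-wave order is not recoverable); a test asserts that permuting
mortality and control changes the output, guarding accidental reordering.
The composable step functions are the reference implementation; the
production loop is a fused in-place kernel asserted equal to their
composition to machine precision.

Burn-in seeds every cell at its class's naive capacity (cover × SNCC) with
the stable age structure and iterates up to 10 000 uncontrolled days,
stopping early if the maximum relative day-to-day change of any cell's
pooled adults falls below 1e-6 (cells under the `floor` of 1e-6 flies are
treated as empty). On the schematic map the criterion levels off around
5e-5 — the small-river lifetable is weakly stable (its net reproduction is
barely above 1 at low density, so its local relaxation is slow) — and
`burn_in()` then warns and returns the state, which is stationary to a few
parts in 1e5 per day; on homogeneous maps the tolerance is reached almost
immediately. An `"equilibrium"` seeding (each cell at its class's exact
lifetable equilibrium, the fixed point of the no-movement model) is
available and is what the movement-disabled comparisons use.

Scenario phases are non-overlapping deployment plans run continuously with
the population carried over. A "year" is 366 days — two full 183-day
target cycles — so the standard reporting window, the 183 days after the
last refreshment, fits exactly; two-year phases are 732 days.

## Outputs and metrics

`percent_remaining()` is 100 × the mean over the window of the daily ratio
of pooled adults to the pre-control baseline, per cell (pooled sexes by
default, matching the field-comparable statistic; zero-baseline cells are
reported missing). `age_fraction()` reports the share of the population
meeting an age condition — ≥ 10 days as the proxy for availability to
stationary baits, > 40 days as "old" because ovarian dissection cannot age
flies beyond about that. `pupal_production_rate()` is daily pupae per
1000 females averaged over a window. `transect()` orders any per-cell
metric along a river from source to mouth.

## Problem sizes and determinism

The simulation itself is fully deterministic; random numbers appear only
in the Monte-Carlo calibration oracles of the test suite, under fixed
seeds. The test suite runs its parameterisation experiments on small
homogeneous maps (3 × 3; with a uniform population, reflecting edges and
equal neighbours every cell is equivalent to the centre of an infinite
map, so this loses nothing) and the spatial experiments on the full
70 × 70 schematic map with a single shared burn-in.

## Known limitations

No seasonality (rates are constant year-round, though dry-season dynamics
near watersheds plausibly matter in the field); no insecticide-resistance
evolution; no disease-transmission layer; aggregate (deterministic) target
degradation rather than per-target loss events; the schematic map is an
approximation, so cell-level absolute values — including whole-map average
abundance — are fixture-dependent and only patterns should be compared
across landscapes.
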