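---
title: "Habitability-driven population diffusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitability-driven population diffusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migflow)
```

## Scope and assumptions

`migflow` models the dispersal of small founding populations into
unoccupied terrain, a regime in which migration can be treated as nearly
deterministic: people move toward land that is flat, low-lying and close to
fresh water, and away from crowding. The model deliberately excludes
everything that makes later migrations complex — farming, resource
accumulation, settlement formation, warfare, and climate gradients. Soil
fertility enters only through water availability. Populations are
real-valued densities on a grid, not discrete agents; "group" identity is
bookkeeping for ancestry, not behavior — all groups obey the same rules and
mix freely.

The native resolution is a 1 km square cell, and one step is interpreted as
roughly one year of drift (a 1 km/year rate of advance), though neither
unit enters the equations: all rates are per cell per step.

## Terrain scoring

Each cell gets four normalized scores.

**Altitude.** `altitude_desirability()` is piecewise in altitude `A` (m):

| band | value |
|---|---|
| `A < 0` (sea) | 0 |
| `0 <= A <= 300` | `(1000 - (7/3) A)/1000` |
| `300 < A <= 2100` | `((A - 300)/9 + 300)/1000` |
| `2100 < A <= 4100` | `(4100 - A)/4000` |
| `A > 4100` | 0 |

The middle band's bounds and expression are fixed by continuity: the four
pieces agree at 300 m (0.3), 2100 m (0.5) and 4100 m (0), reproducing the
observed pattern of settlement density — a steep fall above the coastal
plain, a secondary habitable zone on high plateaus, and a hard ceiling.
Continuity is verified to 1e-9 in the tests.

**Relief.** `local_relief()` compares each cell to the mean of its von
Neumann 5-cell stencil, excluding sea and nodata members (border cells use
the members that exist): `d = |A_mean - A|/1000` up to 300 m, scaled by
`300/A` between 300 and 4100 m (so the same absolute roughness matters less
at altitudes where slopes are unavoidable), and 0 above the altitude
ceiling. `surface_desirability()` maps relief to a score — flat land
(`d <= L_flat`) scores `1 - d/(2 L_flat)`, tolerable land
(`L_flat < d <= L_tol`) scores `L_flat/(2d)`, anything rougher is
uninhabitable — and `surface_class()` returns the matching class. Both
pieces give 0.5 at the `L_flat` breakpoint. `L_flat` defaults to 0.2: it is
the value used consistently with the explicit class table, and the
alternative 0.25 is a constructor argument away.

**Water.** `distance_to_water()` is an exact Euclidean distance (between
cell centers, in km) to the nearest freshwater cell, computed against all
sources; the tests hold it against a brute-force all-pairs minimum. The
default score is 1 within `r_full = 2` km (water can simply be carried),
an inverse-square fall `(r_full/S)^2` out to `r_max = 10` km, and 0 beyond.
Three variants are selectable: a linear ramp over the same range, a doubled
range, and an alternative-constants mode (radii of 10 and 50 cells with a
`S^-0.0435` middle piece) kept for comparison. Where several sources are in
range we score the nearest source rather than summing contributions;
summing can exceed 1 and would break the design rule that every
desirability lies in [0, 1].

**Rating.** `site_rating()` combines the scores by case:
uninhabitable land (or sea/freshwater) rates 0; land with poor water
supply (`D_riv <= 0.5`) rates `D_alt^2 * D_surf`; high land (above 2100 m,
the start of the upper altitude band — the case table itself names no
threshold, so we use the band boundary) rates `(D_alt * D_riv)^4`; flat
land with good water rates `D_surf^2 * D_alt * D_riv`; tolerable land with
good water rates `(D_surf * D_alt * D_riv)^2`. The raw case formulas can
fall below the documented class ranges, so with `rescale_rating = TRUE`
(default) the raw ratings are affinely mapped, per class and per grid, onto
[0.5, 1] for flat land and [0.25, 1] for tolerable land; a class whose raw
ratings are all equal maps to 1. The class minima of 0.5 and 0.25 are
asserted by the acceptance tests whenever the classes are non-empty.

**Capacity.** `optimum_population()` is the arithmetic mean of a
location-based optimum `P_max (0.5 D_surf + 0.5 D_alt)` and a water-based
optimum `P_max D_riv`, zero off habitable land. `P_max = 1e7` persons is
the global ceiling.

`location_desirability()` (`D_loc = W_flat D_surf + (1 - W_flat) D_alt`) is
exported as a diagnostic; the canonical rating uses the case table. The
weight `W_flat` has no canonical value, so it defaults to an uncommitted
0.5 and affects nothing but the diagnostic layer.

## The diffusion engine

The engine's update is the package's central design decision. The source
descriptions of the flux algebra are mutually inconsistent in places (a
rating `R_in + C P` that grows with population would make crowding
attractive; one slope constant simplifies to zero as printed), so the
canonical engine keeps every qualitative contract in one consistent
synchronous update:

1. **Effective ratings** from the pre-step state:
   `R = R_in * max(0, 1 - P/(2 P_best))`, so `R(0) = R_in`,
   `R(P_best) = R_in/2`, and `R = 0` at twice capacity and beyond.
2. **Fluxes**, computed from the pre-step state and applied synchronously.
   Each cell's mobile pool is `M = mu P (1 - R)`: contented people do not
   move. The pool splits among habitable neighbors in proportion to their
   ratings (a neighbor at or above twice its capacity is excluded and its
   share redistributed; if every neighbor rates 0, nobody moves), and of
   each boundary's share the fraction `R_b/(R_a + R_b)` actually crosses,
   the rest staying home. Flow across each boundary carries the source
   cell's group composition.
3. **Births**: `P_g += g * P_g * R` per group, with the step's rating;
   `g = 0.1` per step by default (a 0.1% alternative is documented, and
   `g` is an ordinary config field).
4. **Overcrowding clamp**: birth increments are scaled down where they
   would push a cell past `P_max` (with a warning). Only the increment is
   clamped, so with `g = 0` the update conserves total mass exactly — the
   tests require conservation to 1e-6 relative over 1000 steps, and
   observe it at rounding-error level.

Synchronous application (all fluxes computed before any is applied) avoids
sweep-order artifacts; the alternative would make the result depend on cell
enumeration order. The neighborhood defaults to the von Neumann 4; a
Moore 9 variant is available since both conventions appear in the field.

A `rating_mode = "literal"` engine reproduces the printed piecewise rating
feedback for comparison (`S1` read as `(1 - R_in)/P_best`, the negative
mid-band value clamped into [0, 1]); it raises the rating as a cell fills
below capacity — crowding becomes attractive — which is exactly the
pathology the canonical mode removes.

**Sea crossings.** Land connected-components (4-connectivity; freshwater
cells count as part of a landmass, nodata as sea) are joined by at most one
link per pair: the coastal cell pair with the smallest gap, kept only if
the gap (center distance minus one cell, i.e. the sea actually spanned) is
at most 25 km. A link behaves as an extra boundary with its flux damped by
`cell_size/gap`, so a 25-km crossing is 25 times slower than a land
boundary — the hard cutoff is given, the damping is our choice of the
simplest length-penalized rate. The isolation property (a 40-km strait is
never crossed; a 10-km one eventually is) is asserted end to end.

**Determinism.** The engine has no stochastic terms; `rng_seed` exists for
synthetic terrain only. Re-running a configuration reproduces snapshots
bit-identically, which the tests check with `identical()`.

**Degenerate inputs and numerics.** Cells with `P_best = 0` rate 0 and are
never seeded or populated. Transfers are bounded by the mobile pool, so
populations cannot overdraw; values in `(-1e-9, 0)` arising from float
cancellation are zeroed, anything more negative (or non-finite) aborts with
the step index. Ties (all neighbor weights zero) retain the pool in place.

## Contacts and the distance parameter

`detect_contacts()` records, for every group pair, the first step at which
some cell holds at least `contact_threshold` persons of both groups. The
threshold defaults to 1 person — the sources never define "meeting", and
one person of each ancestry in the same square kilometre is the weakest
defensible notion — and is configurable. Contact times are recorded online
during the run at every step, so they are exact regardless of snapshot
cadence; recomputation from stored snapshots is offered for checking and
is exact when the run was snapshotted every step (the tests do both and
compare). `distance_parameter()` divides by the largest finite contact
time: 0 is "same group", 1 the latest-contacting pair; pairs that never
meet stay infinite and are dropped (with a warning) from
`correlate_distance()`, which computes the Pearson correlation over
upper-triangle pairs after label matching and optional group exclusion,
requiring at least three usable pairs. Geographic zones for
`zone_composition()` are a user-supplied label raster, since no canonical
zone boundaries exist for arbitrary terrain.

## What the synthetic terrains emulate

`make_terrain()` builds parametric landscapes: a uniform plain, a conical
island, two rectangular islands separated by a prescribed sea gap, and a
two-valley island with a central ridge. All templates can carry 1-cell-wide
river polylines (kept clear of the coast so habitable land stays
4-connected — a river that split a landmass would wall off diffusion, since
freshwater cells are not populable), smoothed Gaussian altitude noise, and
isolated +3000 m crags whose stencil footprint produces tolerable and
uninhabitable relief classes. The default fixture suite (a 1x2 pair, a
1x21 strip, a noise-free mirror-symmetric island, and a 50x50 two-valley
island with two seeds) jointly exercises every altitude band and every
surface class, which the tests assert.

These terrains reproduce the *structure* real scoring inputs have — coastal
plains under 300 m, ridges, rivers, sea gaps — not the statistics of real
topography. Passing tests therefore demonstrate that the pipeline's rules
behave as specified, not that any particular real landscape or the
published Britain-scale results are reproduced; the headline real-data
correlation of the source study depends on two external rasters and an
unpublished F\_ST vector and is out of reach of a self-contained test
suite. The acceptance script's correlation demo instead correlates the
distance parameter with inter-seed geographic distance on a synthetic
island — a quantity the package itself computes at run time.

## Problem sizes

The test and acceptance workloads use grids from 1x2 to 50x70 and runs of
up to 2000 steps (the default four 500-step epochs), sizes at which the
full suite completes in well under a minute on a single core while still
exercising saturation, ridge crossing, sea crossing and multi-group
contact. Larger grids scale linearly in cells and steps; the engine is
vectorized over the grid.

## Known limitations

- The rescaled rating is grid-relative: `R_in` values are comparable within
  a run, not across terrains. Disable `rescale_rating` for absolute raw
  ratings.
- The crowding cutoff is a hard threshold; a cell can overshoot twice its
  capacity within a single step (inflow is blocked only from the next step
  on) and crowded neighboring cells can exchange population in a persistent
  two-cycle. This is a faithful consequence of the stated rules, not
  numerical error — the two-cell oracle test reproduces it scalar-exactly.
- Sea links connect one coastal cell pair per landmass pair; a long shared
  coastline does not widen the crossing.
- Group admixture is proportional mixing with no memory: descendants carry
  the per-cell ancestry fractions of their parents' cell, nothing more.
- The literal rating mode is a fidelity companion, not a recommended
  configuration.
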