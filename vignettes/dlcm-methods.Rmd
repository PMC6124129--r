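---
title: "Discrete Laplacian cell mechanics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete Laplacian cell mechanics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlcm)
```

## The model

`dlcm` simulates populations of biological cells distributed over a fixed
tessellation of space into *voxels* — Cartesian cells in 2D or 3D, regular
hexagons, or the polygons of a Voronoi diagram.  Each voxel holds an integer
number of cells `u_i` bounded by a carrying capacity of two; in the tumour
model a voxel may instead hold one dead cell (`u_i = -1`).

The mechanics rest on three assumptions:

1. **Equilibrium at capacity-or-below.**  A population in which every cell
   has a voxel of its own is in mechanical equilibrium: nothing moves.
   Small Brownian wiggling about voxel centres is ignored (active movement,
   e.g. chemotaxis, is modelled separately).
2. **Fast pressure relaxation.**  Overcrowded voxels push on their
   surroundings through a scalar *cellular pressure* `p` that equilibrates
   much faster than any other process, so only the quasi-steady limit is
   solved: `-Lp = s(u)` with `s = 1` at doubly occupied voxels and `s = 0`
   elsewhere, and homogeneous Dirichlet data `p = 0` on the free boundary
   (the empty voxels edge-adjacent to the population).  The time-dependent
   relaxation equation is deliberately out of scope: no relaxation
   time-scale parameter exists anywhere in the package.
3. **Exclusion.**  A cell may only move into a neighbouring voxel holding
   strictly fewer cells than its own.

The pressure gradient across the shared edge of voxels `i` and `j`,
integrated over that edge, gives the *edge current*
`I_ij = (e_ij/d_ij)(p_i - p_j)` with `e_ij` the shared edge length (face
area in 3D) and `d_ij` the centre distance.  Positive currents convert to
movement rates through three conversion factors:

* `D1 I` — into an empty voxel never visited before (pristine matrix),
* `D2 I` — into an empty voxel that once held a cell,
* `D3 I` — the crowding case, doubly occupied into singly occupied.

One usually takes `D1 << D2` (unvisited extracellular matrix is harder to
invade); `D2/D3` weighs boundary expansion against internal rearrangement.
By the discrete divergence theorem the currents over any closed surface sum
to the enclosed sources, so with `D2 = D3` a single interior source's total
escape rate equals the total rate of boundary invasion — the package's
acceptance checks verify this ratio to 1e-10.

Events are sampled with the Gillespie direct method: the waiting time is
exponential at the summed rate and the event is drawn proportionally to its
rate.  Between events, any processes local to cells (signalling ODEs) are
integrated deterministically; the chain is exact because rates are
recomputed from a fresh pressure solve after *every* applied event.

## Discretization choices

* **Laplacian weights.**  `w_ij = e_ij/d_ij`, the two-point flux
  approximation, equivalently P1 finite elements with a lumped mass matrix.
  On structured grids this reduces to the classical 5-/7-point stencils
  (checked entrywise against an independent finite-difference assembly).
  The precise consistent scheme has little influence on model output; this
  is the simplest one.  Because all weights are positive, a discrete
  maximum principle holds: pressures are nonnegative, oxygen never
  increases when a consuming cell is added, and no "negative-weight"
  pathologies of cotangent-style assemblies can occur.
* **Dirichlet imposition.**  The linear system is restricted to the
  populated voxels; boundary voxels simply drop out (their `p = 0` enters
  the right-hand side implicitly).  This keeps the system at its smallest
  well-posed size and makes the exterior exactly zero.  A populated region
  with no free boundary (the grid completely full) is a hard error.
* **Chemotactic drift** (`-div(grad p + p chi1 grad S) = s`): the edge flux
  is discretized as `w_ij [(p_i - p_j) + chi1 * pbar_ij (S_i - S_j)]` with
  `pbar_ij` the arithmetic edge average — a central, second-order choice,
  adequate at the drift magnitudes used here (`chi1 |S_i - S_j|` well below
  the diffusive weight).  Upwinding would be the standard alternative for
  advection-dominated regimes.  The active (pressure-independent) current
  `chi2 w_ij (S_i - S_j)` is added to the pressure current *before* the
  D1/D2/D3 classification; the sensed field never generates moves into
  occupied-at-capacity or dead voxels.
* **Adhesion** enters as a nonpositive current correction
  `d_ij sum_k alpha e_ik min(0, r_ij . r_ik)` over populated neighbours
  `k != j`; corrected rates are floored at zero — a resistance can stop a
  move, never reverse it.
* **Hexagonal lattice.**  Pointy-top hexagons in "odd-r" offset rows with
  centre spacing `h`, giving `e = h/sqrt(3)` (the hexagon side), `d = h`
  and voxel area `sqrt(3)/2 h^2`.  The lattice is trimmed to whole cells;
  no partial boundary hexagons are generated.  The orientation is a fixed
  convention — no model quantity depends on it.
* **Voronoi grids** are built by clipping the bounding box against the
  perpendicular-bisector half-planes of all other seeds (exact for convex
  cells, O(n^2) in the number of seeds, which is ample at simulation grid
  sizes; no external geometry library is required).  Neighbours must share
  an edge of *positive length*: cells that touch only at a point (the
  diagonal pairs of a square of seeds) are not neighbours, which is exactly
  the `e_ij > 0` requirement of the flux discretization.
* **Degenerate inputs.**  Duplicate or collinear seeds, non-positive grid
  extents or voxel sizes, occupancies above capacity and illegal events all
  raise immediate errors; an illegal event signals an engine bug and is
  never silently skipped.

## The event loop

One iteration: (1) solve auxiliary fields (Slit, oxygen) and the pressure;
(2) enumerate movement events plus model-specific events (proliferation,
death, degradation); (3) sample `(tau, event)`; (4) integrate local ODEs to
the event time (or to intervening snapshot times, so recorded signalling
states are synchronous with the snapshot clock); (5) apply the event
atomically.  The ordering "fields before local integration" is a
convention; because rates are frozen over the waiting interval and
recomputed after the event, any consistent ordering yields the same chain.
Local ODEs are one-way coupled (movement rates do not read internal state),
matching all four shipped experiments; two-way coupling would only require
the extra-events hook to read `internalState()`.

Reproducibility: a run is a pure function of (configuration, seed).  The
single RNG stream drives waiting times, event selection and the uniform
choice of which of two co-occupant cells moves; multi-trial experiments use
`seed + trial - 1`.

Performance notes: the pressure system changes support after every event
and is re-factorised each time (direct sparse solve; the restricted system
is small because only the populated region enters).  The oxygen system
matrix is fixed by the grid, so its Cholesky factor is computed once and
only the right-hand side is updated.  Incremental factor updates are a
documented future optimization, not implemented.

## The four experiments and what they emulate

The experiment generators *are* the study conditions; they produce the
initial occupancies and parameter sets in code, and all tests run against
them.

* **Relaxation** (`relaxationExperiment`): a square block of doubly
  occupied voxels (default 10 x 10, grid 40 x 40) relaxes to an absorbing
  all-singly-occupied state.  Averaging the final density over independent
  trials quantifies grid artefacts via the anisotropy ratio
  `max/min second-moment eigenvalue - 1`; the preset tolerance for the
  isotropy checks is 0.05 at 25 trials per grid, chosen as several times
  the sampling noise expected from ~200 cells x 25 trials while still an
  order of magnitude below what a genuinely preferred lattice direction
  would produce.  The initial square itself has equal second moments, so
  any anisotropy is generated, not inherited.
* **Slit chemo-repulsion** (`slitExperiment`): a circular explant of doubly
  occupied voxels (reference radius 10, horizon 1000, 100 trials; the test
  suite runs radius 5, horizon 200, 10 trials) senses the analytic
  steady-state field of a line source `S = Q/(2 sqrt(k D_S)) *
  exp(-sqrt(k/D_S)|x1 - X_s|)` with `(chi1, chi2, D_S, k, Q, X_s) =
  (100, 5, 50, 0.1, 2, 50)`.  Slit repels: the averaged-density centroid
  moves away from the source.
* **Delta-Notch on a growing tissue** (`deltaNotchExperiment`): hexagonal
  grid (51 x 51), circular patch of radius 5 of singly occupied voxels;
  cells whose voxel centre lies in that *fixed* region proliferate at unit
  rate; the run halts at exactly 1000 living cells.  Each living cell
  integrates `n' = f(dbar) - n`, `d' = v (g(n) - d)` with
  `f(x) = x^k/(a + x^k)`, `g(x) = 1/(1 + b x^h)` and
  `(a, b, v, k, h) = (0.01, 100, 1, 2, 2)`; `dbar` is the mean Delta over
  the cell's contacts.  For doubly occupied voxels the contact set is read
  cell-wise: all cells in neighbouring voxels plus the co-occupant, each
  counted once (the simplest cell-count-weighted reading; a voxel-averaged
  alternative would weight co-occupants differently and is easy to swap in
  `cellAdjacency`).  Initial `(n, d)` are drawn uniformly from [0, 1]: the
  homogeneous fixed point is unstable and patterning needs its symmetry
  broken; daughters inherit the mother's state.  At these parameters the
  patterned steady state places roughly two thirds of cells at high Notch,
  and it is the *low*-Notch (high-Delta, primary-fate) cells that form an
  independent set — the property suite asserts exactly that.  Scaling the
  right-hand side by 50 puts signalling in quasi-steady state during
  growth; the monitored per-cell residual (rhs norm divided by the speed
  factor, i.e. the state's distance from its nullcline) is the
  quantitative diagnostic.
* **Avascular tumour** (`tumourExperiment`): 5 x 5 block of singly occupied
  voxels at the centre of a 101 x 101 grid whose outer boundary holds the
  oxygen concentration at 1.  Oxygen solves `-Lc = -lambda a(u)` with
  `a(u)` the number of living cells per voxel.  Kinetics (rates per second,
  strict threshold comparisons): proliferation at `rho_prol = 0.125` where
  `u = 1` and `c > kappa_prol = 0.65`; death at `rho_death = 0.125` where
  `u = 1` and `c < kappa_death = 0.55`; degradation of dead cells at
  `rho_deg = 0.01`; movement with `(D1, D2, D3) = (0.01, 25, 0.01)`,
  `lambda = 0.0015`.  Death is only defined for singly occupied voxels —
  the state space has no mixed live/dead voxel — so a doubly occupied
  hypoxic voxel must first lose a cell by movement.  Dead cells block
  movement and are never sources or oxygen consumers.  For reporting,
  living cells are *proliferation-capable* when their voxel has
  `c > kappa_prol` and *quiescent* otherwise; necrotic means `u = -1`.
  The domain half-width of ~50 voxels fixes where hypoxia bites: the
  central oxygen deficit of a population of `N` cells grows like
  `lambda N log(R/a)`, so by roughly a thousand cells the survival
  threshold is crossed and a necrotic core forms.  The bundled
  `inst/scripts/tumour-calibration.R` implements the radius-first
  parameter-space navigation as a standalone helper.

## What passing tests do and do not show

The experiments generate idealized conditions: uniform lattices, a
closed-form morphogen profile, noiseless ODEs, oxygen in quasi-steady
state, and parameters constant in time.  Tests passing on them verify the
discretization, the exactness of the event sampling, conservation and
capacity invariants, isotropy of the mechanics, and the qualitative phase
structure of the coupled models.  They do not validate the biology of any
particular tissue: real cell populations have heterogeneous sizes and
rates, mechanics beyond a scalar pressure (the missing surface adhesion is
precisely why the tumour model eventually grows protrusions rather than
reaching a steady radius), and measured rather than assumed `D1/D2`
separations.

## Problem sizes used by the shipped checks

Chosen so the whole suite runs comfortably on a single CPU: relaxation
isotropy at 25 trials per grid on 40 x 40 grids; the Slit repulsion at 10
trials, radius 5, horizon 200; the Delta-Notch growth run at its full
1000-cell target; the tumour run on the reference 101 x 101 grid until the
first necrotic voxel (horizon 800 s); oracle-equivalence solves on
100-voxel grids; Gillespie statistics at 1e5 samples.

## Known limitations

* Quasi-steady pressure only; no time-dependent relaxation, no Robin
  ("semi-free") boundaries, and Neumann walls are not exercised by any
  shipped experiment.
* Carrying capacity is fixed at two cells per voxel.
* 3D is Cartesian only; Voronoi grids are 2D.
* The linear solves are direct; very large populations would want
  multigrid or incremental factorizations.
* Cell identity is tracked (ids are never reused) but no lineage tree is
  built, and visited flags never decay.
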