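# dlcm: discrete Laplacian cell mechanics

`dlcm` is an event-driven, continuous-time simulator for populations of
biological cells on voxel grids, aimed at modellers of tissue growth,
collective migration and tumour spheroids who want cell-level stochasticity
with a constitutive, PDE-grounded description of mechanics — at a cost that
scales to thousands of cells on a laptop.

Cells live on a tessellation (Cartesian 2D/3D, hexagonal, or unstructured
Voronoi) with at most two cells per voxel.  Voxels above one cell act as
unit sources of a *cellular pressure* governed by the quasi-steady discrete
Laplace equation

    -L p = s(u),   s(u_i) = 1 if u_i = 2, else 0,   p = 0 on the free boundary,

where `L` has edge weights `w_ij = e_ij/d_ij` (shared edge length over
centre distance).  The pressure gradient integrated across an edge,
`I_ij = w_ij (p_i - p_j)`, converts to stochastic movement rates through
three factors: `D1` (into never-visited empty voxels), `D2` (into
previously visited empty voxels) and `D3` (crowding moves into singly
occupied voxels).  Events — moves, proliferation, death, degradation — are
sampled exactly with the Gillespie direct method, and per-cell ODEs
(e.g. Delta–Notch lateral inhibition) are integrated between events, so
signalling and mechanics share one continuous clock.  Couplings to
chemotactic fields (drift in the pressure equation plus an active
down-gradient current) and to oxygen-limited tumour kinetics are built in.

## Worked example

A 1×3 strip of occupied voxels, the middle one doubly occupied, on a 7×5
grid:

```r
library(dlcm)
g <- buildStructuredGrid("cartesian2d", c(7, 5))
u <- integer(35); u[c(17, 19)] <- 1L; u[18] <- 2L   # strip A, B, C at row 3
s <- initializeState(g, occupancy = u)

p <- computePressure(s, g)
p[17:19]
#> [1] 0.07142857 0.28571429 0.07142857
```

The restricted system solves to `p = (1/14, 2/7, 1/14)`: the overcrowded
centre voxel pushes hardest, its singly occupied neighbours feel a
fourteenth of the source strength.  Converting edge currents to rates with
`D1 = D2 = D3 = 1`:

```r
ev <- enumerateMoveEvents(s, g, p, rateConstants(D1 = 1, D2 = 1, D3 = 1))
ev
#> EventSet: 10 events, total rate 1.42857
totalRate(ev)                                   # 10/7
#> [1] 1.428571
sum(eventTable(ev)$rate[u[eventTable(ev)$to] == 0])
#> [1] 1
```

Ten moves are possible (each end cell into its three empty neighbours, the
centre cells into either end or their two empty sides).  The rates into
empty voxels sum to exactly 1 — the discrete divergence theorem: the total
flux through the population's boundary equals the one enclosed source.
`runSimulation()` then draws an exponential waiting time at rate 10/7,
picks a move proportionally to its rate, applies it, and re-solves.

The four study pipelines are one call each, e.g.

```r
res <- tumourExperiment(horizon = 800, seed = 1, stopAtNecrosis = TRUE)
res$firstQuiescentTime; res$firstDeathTime
#> [1] 296.7991
#> [1] 360.6916
```

— starting from a 5×5 block the tumour grows exponentially while oxygen is
plentiful, develops a quiescent annulus (here at t ≈ 297 s) and then a
necrotic core (first death at t ≈ 361 s).  `relaxationExperiment()`,
`slitExperiment()` and `deltaNotchExperiment()` cover isotropic relaxation,
chemo-repulsion of an explant and lateral-inhibition patterning on a
growing tissue; `runExperiment(loadConfig("cfg.yaml"), outdir = "run/")`
drives any of them from a YAML file, as does the `inst/scripts/dlcm`
command-line wrapper.

See `vignettes/dlcm-methods.Rmd` for the model assumptions, discretization
and design decisions.

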