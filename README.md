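# knotrelax

Type-II topoisomerase (TopoII) passes one DNA double helix through a
transient cut in another, and in doing so unties the knots that replication
and recombination leave on circular DNA. Almost all polymer models of this
process keep the TopoII-bound region fixed in place, yet real TopoII binds,
slides and unbinds on sub-second timescales. `knotrelax` is a simulation
and analysis toolkit for asking what that *dynamics* does to topological
relaxation: it implements a coarse-grained knotted DNA ring with a mobile
strand-crossing segment, measures how fast the knotting probability decays
under five binding models, and distils the mechanism into an idealised
two-dimensional random walk over knot spaces.

The package is aimed at polymer and DNA-topology researchers who want a
self-contained, scriptable engine (no external MD code) whose every
observable is unit-tested against independent oracles.

## Model

A nicked plasmid is a ring of N beads (sigma = 2.5 nm each) with

* purely repulsive truncated-shifted Lennard-Jones sterics,
  U_LJ = 4e[(s/r)^12 - (s/r)^6] + e for r < 2^(1/6) s;
* FENE bonds, -0.5 K R0^2 log(1 - (r/R0)^2), K = 30 e/s^2, R0 = 1.6 s;
* Kratky-Porod stiffness (k_BT l_p / s)(1 - cos phi), l_p = 20 s = 50 nm;
* one soft segment of l_T = 50 beads, the TopoII footprint, interacting via
  U_s = A(1 + cos(pi r / r_c)) with A = 2 k_BT - finite at contact, so
  strands cross it at a Boltzmann-weighted rate.

Langevin dynamics (BAOAB velocity Verlet, dt = 0.01 tau_B, gamma = 1).
The soft segment is relocated by one of five models: `static`, `jump`
(uniform, rate k_j), `diffuse` (one bead per 1/k_d, D = 0.5 k_d s^2),
`max_curvature` and `max_density` (deterministic jumps to the argmax of a
windowed curvature, Eq-5 style, or a local-density count - both violating
detailed balance on purpose). Topology is tracked with the Alexander
determinant |A(-1)| (re-implemented from scratch: seeded generic
projection, underpass presentation, exact integer determinant) and the
shortest physically knotted arc found by minimally interfering closure.

## Worked example

Map simulation units to physical ones, then watch a density-biased TopoII
untie a 5_1 knot on a small ring:

```r
library(knotrelax)

u <- physical_units()
cat("tau_B:", u$reported$tau_B_ns, "ns  k_off:", u$reported$k_off_s,
    "1/s  K_d:", u$reported$K_d_nM, "nM\n")
#> tau_B: 40 ns  k_off: 250 1/s  K_d: 50 nM

ring <- make_torus_knot(120, 5)                  # 5_1 torus knot, 120 beads
p    <- sim_params(N = 120, lp = 5, seed = 7)
ring <- equilibrate_fixed_topology(ring, p, 5e4, seed = 7)

knot_report(ring)
#> knot_report: |A(-1)| = 5 (knotted, arc 120..89, l_k = 90)

topo <- topo2_state(start_index = 1, l_T = 20, mode = "max_density",
                    k_j = 1e-2)
traj <- simulate_topo2(ring, p, topo, n_steps = 3e5, sample_every = 5e3,
                       seed = 8)
tr <- trace_topology(traj)
tail(tr$det, 1)   # 1: the ring reached the unknot
#> [1] 1
nrow(traj$events) # TopoII relocations along the way
#> [1] 42
```

The report says the 5_1 knot spans 90 of 120 beads (`l_k`); over 3000
tau_B the segment relocated 42 times and the determinant dropped 5 -> 1.
Ensemble curves come from `knotting_probability()` (blocking-method
errors), decay times from `fit_decay()`, and the disk-world analogue from
`build_layout()` + `run_ensemble()`.

A command-line interface covers the same pipeline
(`kr_cli(c("fixtures", ...))`, subcommands `defaults`, `fixtures`,
`simulate`, `analyze`, `walk`), reading `key = value` configs and writing
XYZ / LAMMPS-dump-style trajectories, TSV tables and a reproducibility
manifest.

## Layout

* `R/`, `src/` - engine (Rcpp), TopoII kernels, knot toolkit, observables,
  disk walk, IO/CLI
* `tests/testthat/` - oracle-backed unit and property tests;
  `test-acceptance.R` holds the acceptance criteria
* `vignettes/topological-relaxation.Rmd` - the methods notes: model,
  conventions, scaled-down worlds, known limitations
* `scripts/acceptance.R` - the acceptance report
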