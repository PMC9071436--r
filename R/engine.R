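#' Per-bead forces
#'
#' Analytic gradients (-dU/dr) of the full force field: FENE + steric LJ on
#' bonds, Kratky-Porod bending, LJ or soft non-bonded pairs. Computed by the
#' compiled engine; checked in the test suite against central finite
#' differences of [total_energy()].
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces (k_BT / sigma)
#' @export
compute_forces <- function(conf, params, soft_start = NULL, l_T = 0,
                           A = params$A_soft) {
  x <- as.matrix(conf)
  cpp_forces(x, if (is.null(soft_start)) 1L else as.integer(soft_start),
             as.integer(l_T), A,
             params$sigma, params$epsilon, params$K_fene, params$R0,
             params$lp, params$temperature)
}

new_trajectory <- function(raw, params, mode = "static") {
  structure(list(frames = raw$frames, times = raw$times,
                 seg_start = raw$seg_start, amplitude = raw$amplitude,
                 energies = raw$energies, events = raw$events,
                 x_final = raw$x_final, v_final = raw$v_final,
                 neighbor_rebuilds = raw$neighbor_rebuilds,
                 params = params, mode = mode),
            class = "kr_trajectory")
}

#' @export
print.kr_trajectory <- function(x, ...) {
  cat("kr_trajectory:", dim(x$frames)[3], "frames of N =", dim(x$frames)[1],
      "beads, t =", x$times[1], "...", tail(x$times, 1), "tau_B, mode =",
      x$mode, "\n")
  invisible(x)
}

#' Langevin dynamics run
#'
#' Evolves a ring with the BAOAB velocity-Verlet Langevin integrator at
#' k_BT = `params$temperature`, friction `params$gamma`. With
#' `gamma = 0, temperature = 0` (and explicit `v0`) the integrator reduces to
#' plain velocity Verlet (NVE), which the tests use to verify energy
#' conservation. Trajectories are bitwise reproducible for a given seed.
#'
#' @param conf starting [ring_conformation()]
#' @param params [sim_params()]
#' @param n_steps number of time steps
#' @param sample_every record a frame every this many steps
#' @param soft_start,l_T,A static soft segment (l_T = 0: none)
#' @param v0 optional N x 3 initial velocities; default Maxwell-Boltzmann
#' @param seed RNG seed (defaults to `params$seed`)
#' @return a `kr_trajectory`: frames (N x 3 x n_frames array), times,
#'   per-frame energies, final coordinates and velocities
#' @export
langevin_run <- function(conf, params, n_steps, sample_every = 100L,
                         soft_start = NULL, l_T = 0, A = params$A_soft,
                         v0 = NULL, seed = params$seed) {
  x <- as.matrix(conf)
  raw <- cpp_run(x, v0,
                 params$sigma, params$epsilon, params$K_fene, params$R0,
                 params$lp, params$dt, params$gamma, params$temperature,
                 0L, if (is.null(soft_start)) 1L else as.integer(soft_start),
                 as.integer(l_T), A, params$A_unbind,
                 0, 0, 0, 0L,
                 as.numeric(n_steps), as.integer(sample_every),
                 as.integer(seed))
  new_trajectory(raw, params, mode = if (l_T > 0) "static" else "plain")
}

#' Equilibrate at fixed topology
#'
#' Langevin run with purely repulsive LJ everywhere (no soft segment), so the
#' knot type cannot change; the Alexander determinant is verified before and
#' after and any change aborts (it would indicate integration instability).
#' The full-scale protocol equilibrates for at least one chain relaxation
#' time (1e5 tau_B at N = 500); shorter runs are reported in the returned
#' attributes so scaled-down tests are explicit about their shortfall.
#'
#' @inheritParams langevin_run
#' @return the final [ring_conformation()], with attributes `det`
#'   (Alexander determinant) and `n_steps`
#' @export
equilibrate_fixed_topology <- function(conf, params, n_steps,
                                       seed = params$seed,
                                       sample_every = max(1L, as.integer(n_steps))) {
  d0 <- alexander_det(conf, seed = seed)
  if (n_steps == 0) {
    out <- ring_conformation(as.matrix(conf))
  } else {
    traj <- langevin_run(conf, params, n_steps, sample_every = sample_every,
                         l_T = 0, seed = seed)
    out <- ring_conformation(traj$x_final)
  }
  d1 <- alexander_det(out, seed = seed)
  if (d1 != d0)
    stop("topology changed during LJ-only equilibration (", d0, " -> ", d1,
         "): integration instability")
  attr(out, "det") <- d1
  attr(out, "n_steps") <- n_steps
  out
}
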