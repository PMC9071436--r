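#' TopoII binding state
#'
#' Location, length and relocation model of the single bound (soft) segment.
#' Exactly one segment is bound at all times; the five models are
#' \describe{
#'   \item{static}{never relocates (both rates zero)}
#'   \item{jump}{relocates to a uniformly random site at rate `k_j`}
#'   \item{diffuse}{slides by one bead (either direction) every `1/k_d`,
#'     i.e. curvilinear diffusion with D = 0.5 k_d sigma^2}
#'   \item{max_curvature}{at rate `k_j`, jumps so the segment is centred on
#'     the bead of maximum windowed curvature (violates detailed balance)}
#'   \item{max_density}{at rate `k_j`, jumps to the bead with the most beads
#'     within `R_density` (violates detailed balance)}
#' }
#'
#' @param start_index 1-based first bead of the bound segment
#' @param l_T segment length in beads (default 50, i.e. 360 bp)
#' @param mode one of the five models
#' @param k_j jump rate (1/tau_B) for jump / max_curvature / max_density
#' @param k_d diffusion rate (1/tau_B); D = 0.5 k_d sigma^2
#' @param R_density neighbourhood radius for max_density, default
#'   `50^0.588` sigma (Flory scaling of the 50-bead segment)
#' @param ramp_duration steps spent at `A_unbind` before a relocation
#' @return an object of class `topo2_state`
#' @export
topo2_state <- function(start_index = 1L, l_T = 50L,
                        mode = c("static", "jump", "diffuse",
                                 "max_curvature", "max_density"),
                        k_j = 0, k_d = 0,
                        R_density = 50^0.588, ramp_duration = 100L) {
  mode <- match.arg(mode)
  stopifnot(l_T >= 1, k_j >= 0, k_d >= 0, R_density > 0, ramp_duration >= 0)
  if (mode == "static" && (k_j > 0 || k_d > 0))
    stop("mode 'static' requires both rates to be zero")
  if (mode %in% c("jump", "max_curvature", "max_density") && k_j <= 0)
    stop("mode '", mode, "' requires k_j > 0")
  if (mode == "diffuse" && k_d <= 0)
    stop("mode 'diffuse' requires k_d > 0")
  structure(list(start_index = as.integer(start_index), l_T = as.integer(l_T),
                 mode = mode, k_j = k_j, k_d = k_d,
                 R_density = R_density, ramp_state = "bound",
                 ramp_duration = as.integer(ramp_duration)),
            class = "topo2_state")
}

mode_code <- function(mode) {
  match(mode, c("static", "jump", "diffuse", "max_curvature", "max_density")) - 1L
}

#' Bead of maximum windowed curvature
#'
#' Returns the index i maximising
#' \eqn{\sum_{j=-l_T/2}^{l_T/2} [1 - \hat t_{i+j} \cdot \hat t_{i+j+1}]}
#' over a window of `l_T + 1` consecutive joints (periodic indices), with
#' ties broken by the lowest index. Invariant under rigid motions.
#'
#' @param conf a [ring_conformation()]
#' @param l_T window length in beads
#' @return 1-based bead index
#' @export
select_max_curvature <- function(conf, l_T = 50L) {
  x <- as.matrix(conf)
  if (nrow(x) <= l_T) stop("ring must be longer than the curvature window")
  if (any(bond_lengths(x) == 0)) stop("degenerate (zero-length) bond vector")
  cpp_select_maxcurv(x, as.integer(l_T))
}

#' Bead of maximum local density
#'
#' Returns the index i maximising the number of beads j (including j = i)
#' with |r_i - r_j| < R; ties broken by the lowest index.
#'
#' @param conf a [ring_conformation()]
#' @param R_density neighbourhood radius (sigma)
#' @return 1-based bead index
#' @export
select_max_density <- function(conf, R_density = 50^0.588) {
  cpp_select_maxdens(as.matrix(conf), R_density)
}

#' Update the binding state over an elapsed time
#'
#' Pure bookkeeping realisation of the relocation kernels, used for
#' distributional tests without running dynamics. Jump-type relocations are
#' drawn as exponential waiting times at rate `k_j` (Gillespie style);
#' diffusion moves the segment by one bead every `1/k_d`. Uses R's RNG
#' (set a seed for reproducibility).
#'
#' @param topo a [topo2_state()]
#' @param conf a [ring_conformation()] (consulted by the biased modes)
#' @param elapsed_time time window in tau_B
#' @return list with the updated `state` and an `events` data frame
#'   (time, old_index, new_index, mode)
#' @export
update_binding <- function(topo, conf, elapsed_time) {
  N <- nrow(as.matrix(conf))
  ev_t <- numeric(0); ev_o <- integer(0); ev_n <- integer(0)
  start <- topo$start_index
  if (topo$mode %in% c("jump", "max_curvature", "max_density")) {
    t <- rexp(1, topo$k_j)
    while (t <= elapsed_time) {
      new <- switch(topo$mode,
        jump = sample.int(N, 1),
        max_curvature = centre_segment(select_max_curvature(conf, topo$l_T),
                                       topo$l_T, N),
        max_density = centre_segment(select_max_density(conf, topo$R_density),
                                     topo$l_T, N))
      ev_t <- c(ev_t, t); ev_o <- c(ev_o, start); ev_n <- c(ev_n, new)
      start <- new
      t <- t + rexp(1, topo$k_j)
    }
  } else if (topo$mode == "diffuse") {
    n_moves <- floor(elapsed_time * topo$k_d)
    if (n_moves > 0) {
      steps <- sample(c(-1L, 1L), n_moves, replace = TRUE)
      pos <- ((start - 1L + cumsum(steps)) %% N) + 1L
      ev_t <- seq_len(n_moves) / topo$k_d
      ev_o <- c(start, pos[-n_moves])
      ev_n <- pos
      start <- pos[n_moves]
    }
  }
  topo$start_index <- start
  list(state = topo,
       events = data.frame(time = ev_t, old_index = ev_o, new_index = ev_n,
                           mode = rep(topo$mode, length(ev_t))))
}

centre_segment <- function(i, l_T, N) {
  ((i - 1L - l_T %/% 2L) %% N) + 1L
}

#' Schedule an unbinding ramp
#'
#' Before a relocation the soft segment's amplitude is raised to `A_unbind`
#' for `ramp_duration` steps (expelling any strand trapped inside it), after
#' which its pairs revert to plain LJ and the segment at the new location
#' becomes soft at `A_soft`. This returns the state flagged as ramping plus
#' the amplitude schedule the engine applies; overlapping ramps are
#' serialised by construction (a new relocation waits for the running ramp).
#'
#' @param topo a [topo2_state()]
#' @param params [sim_params()]
#' @return list(state, schedule): schedule has one row per phase with the
#'   amplitude and duration (steps)
#' @export
unbind_ramp <- function(topo, params) {
  topo$ramp_state <- "ramping"
  list(state = topo,
       schedule = data.frame(
         phase = c("ramp", "rebind"),
         amplitude = c(params$A_unbind, params$A_soft),
         duration_steps = c(topo$ramp_duration, NA_integer_)))
}

#' Simulate the ring with dynamic TopoII binding
#'
#' Full Langevin run in which the soft segment relocates according to the
#' binding model in `topo`. Jump-type relocations first execute the
#' unbinding ramp (segment at `A_unbind` for `ramp_duration` steps, extended
#' while a strand is still trapped within 0.9 sigma); diffusion slides the
#' bound segment without unbinding. Biased modes evaluate their argmax at
#' the moment of the jump.
#'
#' @inheritParams langevin_run
#' @param topo a [topo2_state()]
#' @return a `kr_trajectory`; `$events` logs every relocation
#'   (time, old_index, new_index) and `$seg_start` gives the per-frame
#'   segment location
#' @export
simulate_topo2 <- function(conf, params, topo, n_steps, sample_every = 100L,
                           v0 = NULL, seed = params$seed) {
  x <- as.matrix(conf)
  raw <- cpp_run(x, v0,
                 params$sigma, params$epsilon, params$K_fene, params$R0,
                 params$lp, params$dt, params$gamma, params$temperature,
                 mode_code(topo$mode), topo$start_index, topo$l_T,
                 params$A_soft, params$A_unbind,
                 topo$k_j, topo$k_d, topo$R_density, topo$ramp_duration,
                 as.numeric(n_steps), as.integer(sample_every),
                 as.integer(seed))
  tr <- new_trajectory(raw, params, mode = topo$mode)
  tr$topo <- topo
  tr
}
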