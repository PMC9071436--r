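#' Pair interaction energy
#'
#' Truncated-and-shifted Lennard-Jones repulsion (the default steric
#' interaction) or the soft strand-crossing potential used for pairs that
#' involve the TopoII-bound segment. Both vanish continuously at the cutoff
#' `rc = 2^(1/6) sigma`:
#' \deqn{U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon}
#' \deqn{U_s(r) = A (1 + \cos(\pi r / r_c))}
#' The soft potential is finite everywhere (value `2A` at r = 0), which is
#' what permits strand crossing at a Boltzmann-weighted rate.
#'
#' @param r inter-bead distance(s), units of sigma
#' @param kind "LJ" or "soft"
#' @param params [sim_params()]
#' @param A soft amplitude in k_BT (defaults to `params$A_soft`)
#' @return energy in k_BT, vectorised over `r`
#' @export
#' @examples
#' p <- sim_params(N = 10)
#' pair_energy(1, "LJ", p)            # epsilon (the shift)
#' pair_energy(0, "soft", p, A = 2)   # 2A = 4
pair_energy <- function(r, kind = c("LJ", "soft"), params, A = params$A_soft) {
  kind <- match.arg(kind)
  stopifnot(all(r >= 0))
  rc <- params$rc
  out <- numeric(length(r))
  inside <- r < rc
  if (kind == "LJ") {
    if (any(r[inside] == 0))
      stop("singular overlap: r = 0 with the LJ potential")
    s6 <- (params$sigma / r[inside])^6
    out[inside] <- 4 * params$epsilon * (s6^2 - s6) + params$epsilon
  } else {
    out[inside] <- A * (1 + cos(pi * r[inside] / rc))
  }
  out
}

#' Bonded energy of a ring conformation
#'
#' FENE bond energy and Kratky-Porod bending energy. The bending term is
#' \eqn{(k_BT l_p/\sigma)(1 + \cos\theta)} with the MD-engine convention that
#' \eqn{\theta} is the angle between consecutive bond vectors measured so a
#' straight chain has \eqn{\theta = \pi} and zero energy; equivalently
#' \eqn{\kappa(1 - \hat t_i \cdot \hat t_{i+1})}.
#'
#' @param conf a [ring_conformation()]
#' @param params [sim_params()]
#' @return list with `fene` and `bend` totals (k_BT) plus the per-bond and
#'   per-vertex contributions
#' @export
bonded_energy <- function(conf, params) {
  x <- as.matrix(conf)
  n <- nrow(x)
  b <- x[c(2:n, 1), , drop = FALSE] - x           # bond vectors t_i
  r2 <- rowSums(b^2)
  bad <- which(r2 >= params$R0^2)
  if (length(bad))
    stop("FENE domain violation (r >= R0) at bond starting at bead ", bad[1])
  fene <- -0.5 * params$K_fene * params$R0^2 * log(1 - r2 / params$R0^2)
  bn <- b / sqrt(r2)
  cosang <- rowSums(bn * bn[c(2:n, 1), , drop = FALSE])
  kappa <- params$temperature * params$lp / params$sigma
  if (params$temperature == 0) kappa <- params$lp / params$sigma
  bend <- kappa * (1 - cosang)
  list(fene = sum(fene), bend = sum(bend),
       fene_bonds = fene, bend_vertices = bend)
}

#' Total potential energy (reference R implementation)
#'
#' Sums pair, FENE and bending energies over a conformation. This is an
#' independent O(N^2) R implementation used as the oracle for the compiled
#' force routine (forces are checked against its finite differences).
#'
#' @inheritParams bonded_energy
#' @param soft_start 1-based first bead of the soft segment, or NULL
#' @param l_T segment length in beads (0 = no soft segment)
#' @param A soft amplitude
#' @return total energy in k_BT
#' @export
total_energy <- function(conf, params, soft_start = NULL, l_T = 0,
                         A = params$A_soft) {
  x <- as.matrix(conf)
  n <- nrow(x)
  be <- bonded_energy(conf, params)
  dmat <- as.matrix(dist(x))
  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  d_cyc <- pmin(idx[, 2] - idx[, 1], n - (idx[, 2] - idx[, 1]))
  rr <- dmat[idx]
  inseg <- rep(FALSE, n)
  if (l_T > 0 && !is.null(soft_start))
    inseg[((soft_start - 1 + 0:(l_T - 1)) %% n) + 1] <- TRUE
  soft_pair <- (inseg[idx[, 1]] | inseg[idx[, 2]]) & d_cyc > 1
  epair <- numeric(length(rr))
  lj <- !soft_pair
  epair[lj] <- pair_energy(rr[lj], "LJ", params)
  if (any(soft_pair))
    epair[soft_pair] <- pair_energy(rr[soft_pair], "soft", params, A = A)
  sum(epair) + be$fene + be$bend
}
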