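#' Simulation parameters
#'
#' Collects the force-field and integrator constants for the bead-spring
#' ring in reduced units (sigma = epsilon = k_BT = tau_B = 1).
#'
#' @param N number of beads in the ring (default 500)
#' @param sigma bead diameter, the length unit (2.5 nm)
#' @param epsilon energy unit, equal to k_BT
#' @param A_soft soft (strand-crossing) amplitude in k_BT
#' @param A_unbind amplitude of the unbinding ramp in k_BT
#' @param K_fene FENE spring constant (epsilon/sigma^2)
#' @param R0 maximum FENE bond extension (sigma)
#' @param lp persistence length in units of sigma
#' @param dt integration time step (tau_B)
#' @param gamma Langevin friction (1/tau_B)
#' @param temperature k_BT in reduced units
#' @param seed integer RNG seed
#'
#' @return an object of class `sim_params` (a validated list; `rc` is always
#'   `2^(1/6) * sigma`)
#' @export
#' @examples
#' p <- sim_params(N = 100, lp = 10)
#' p$rc / p$sigma  # 2^(1/6)
sim_params <- function(N = 500, sigma = 1, epsilon = 1,
                       A_soft = 2, A_unbind = 20,
                       K_fene = 30, R0 = 1.6, lp = 20,
                       dt = 0.01, gamma = 1, temperature = 1, seed = 1L) {
  p <- list(N = as.integer(N), sigma = sigma, epsilon = epsilon,
            A_soft = A_soft, A_unbind = A_unbind, K_fene = K_fene,
            R0 = R0, lp = lp, rc = 2^(1 / 6) * sigma,
            dt = dt, gamma = gamma, temperature = temperature,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$N >= 3,
            p$sigma > 0, p$epsilon > 0,
            p$dt > 0, p$dt < 0.05,
            p$R0 > p$sigma,
            p$A_soft > 0, p$A_unbind > p$A_soft,
            p$gamma >= 0, p$temperature >= 0,
            isTRUE(all.equal(p$rc, 2^(1 / 6) * p$sigma)))
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params: N =", x$N, " lp =", x$lp, "sigma",
      " dt =", x$dt, "tau_B  gamma =", x$gamma,
      " A_soft =", x$A_soft, " A_unbind =", x$A_unbind, "\n")
  invisible(x)
}
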