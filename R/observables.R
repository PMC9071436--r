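#' Ensemble knotting probability with blocking errors
#'
#' P_K(t) is the fraction of replicas whose determinant differs from 1 at
#' each sampled time. Because knottedness is binary, the SEM comes from the
#' blocking method: replicas are randomly partitioned into `n_blocks` blocks,
#' per-block means are computed, and the standard error across blocks is
#' reported.
#'
#' @param traces list of topology traces ([trace_topology()]) on a common
#'   time grid
#' @param n_blocks number of blocks (default 8)
#' @param seed seed for the random partition
#' @return data frame of class `relaxation_curve`: time, P_K, sem
#' @export
knotting_probability <- function(traces, n_blocks = 8L, seed = 1L) {
  stopifnot(length(traces) >= 2)
  if (length(traces) < n_blocks)
    stop("fewer replicas (", length(traces), ") than blocks (", n_blocks, ")")
  times <- traces[[1]]$time
  for (tr in traces)
    if (length(tr$time) != length(times) || any(tr$time != times))
      stop("traces are not on a common time grid")
  km <- vapply(traces, function(tr) as.numeric(tr$det != 1),
               numeric(length(times)))          # time x replica
  p <- rowMeans(km)
  nrep <- length(traces)
  part <- local_seed_sample(seed, n_blocks, nrep)
  bm <- vapply(seq_len(n_blocks),
               function(b) rowMeans(km[, part == b, drop = FALSE]),
               numeric(length(times)))          # time x block
  sem <- apply(bm, 1, sd) / sqrt(n_blocks)
  structure(data.frame(time = times, P_K = p, sem = sem),
            class = c("relaxation_curve", "data.frame"), n_replicas = nrep)
}

# seeded block partition that leaves the caller's RNG stream untouched
local_seed_sample <- function(seed, n_blocks, nrep) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(rep(seq_len(n_blocks), length.out = nrep))
}

#' Rate of topology-changing events
#'
#' Number of consecutive-sample pairs with differing determinant divided by
#' the total simulated time. Resolution dependent: the sampling interval is
#' part of the reported quantity (coarser sampling can only coalesce events,
#' never create them).
#'
#' @param trace a topology trace
#' @return events per tau_B
#' @export
topology_change_rate <- function(trace) {
  stopifnot(nrow(trace) >= 2)
  ttot <- trace$time[nrow(trace)] - trace$time[1]
  sum(diff(trace$det) != 0) / ttot
}

#' Maximum knot determinant after leaving the initial topology
#'
#' The maximum of |A(-1)| over all samples from the first departure from
#' `initial_det` onward; 1 (the unknot value, by convention) if the topology
#' never changes.
#'
#' @param trace a topology trace
#' @param initial_det determinant of the initial topology (default: first
#'   sample)
#' @export
max_alexander <- function(trace, initial_det = trace$det[1]) {
  stopifnot(nrow(trace) >= 1)
  i0 <- which(trace$det != initial_det)[1]
  if (is.na(i0)) return(1)
  max(trace$det[i0:nrow(trace)])
}

#' Early-time exponential decay fit
#'
#' Least-squares fit of exp(-t/tau) to a knotting-probability curve. The
#' default window keeps the early times where P_K exceeds 1/e of its initial
#' value; a fixed time window can be given instead. A curve that never
#' decays returns the infinity sentinel.
#'
#' @param curve a `relaxation_curve` (or data frame with time and P_K)
#' @param window NULL for the 1/e rule, or c(tmin, tmax) in tau_B
#' @return list(tau, n_points, converged, rss); tau = Inf for non-decaying
#'   input
#' @export
fit_decay <- function(curve, window = NULL) {
  t <- curve$time; p <- curve$P_K
  p0 <- p[1]
  if (is.null(window)) {
    below <- which(p < p0 / exp(1))
    imax <- if (length(below)) below[1] else length(p)
    keep <- seq_len(max(imax, 3))
    keep <- keep[keep <= length(p)]
  } else {
    keep <- which(t >= window[1] & t <= window[2])
  }
  t <- t[keep]; p <- p[keep]
  if (all(p >= p0 - .Machine$double.eps) || length(t) < 2)
    return(list(tau = Inf, n_points = length(t), converged = FALSE, rss = NA))
  # start value from the log-linear fit through the positive samples
  pos <- p > 0
  tau0 <- tryCatch(-1 / coef(lm(log(p[pos]) ~ t[pos] + 0))[[1]],
                   error = function(e) NA)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t[t > 0], 1)
  fit <- tryCatch(
    suppressWarnings(nls(p ~ exp(-t / tau), start = list(tau = tau0),
                         control = list(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (is.finite(tau0) && tau0 > 0)
      return(list(tau = tau0, n_points = length(t), converged = FALSE,
                  rss = sum((p - exp(-t / tau0))^2)))
    return(list(tau = Inf, n_points = length(t), converged = FALSE, rss = NA))
  }
  list(tau = coef(fit)[["tau"]], n_points = length(t),
       converged = TRUE, rss = sum((p - fitted(fit))^2))
}

#' Scaling of the topological relaxation time with substrate length
#'
#' For a static strand-crossing segment the knotted portion (length l_k ~
#' N^theta) must find the segment by curvilinear diffusion with D_k ~
#' D_0/l_k, giving tau_R ~ (N - l_k)^2 l_k / D_0 ~ N^(2+theta); a jumping
#' segment only needs to land on the knotted arc, tau_T ~ (N/l_k)/k_j ~
#' N^(1-theta). Their ratio grows as N^(2 theta + 1).
#'
#' @param N substrate length (beads)
#' @param theta_exponent knot-length scaling exponent, 0 < theta <= 1
#' @param l_k knot length (default N^theta)
#' @return list with tau_R_scaling, tau_T_scaling, their exponents and the
#'   asymptotic ratio exponent 2 theta + 1
#' @export
scaling_predictions <- function(N, theta_exponent, l_k = N^theta_exponent) {
  stopifnot(theta_exponent > 0, theta_exponent <= 1)
  tau_R <- (N - l_k)^2 * l_k       # (N-l_k)^2 / D_k, D_k = D_0 / l_k
  tau_T <- N / l_k                 # inverse landing probability, per 1/k_j
  list(tau_R_scaling = tau_R, tau_T_scaling = tau_T,
       tau_R_exponent = 2 + theta_exponent,
       tau_T_exponent = 1 - theta_exponent,
       ratio_exponent = 2 * theta_exponent + 1)
}

#' Map reduced units to physical units
#'
#' Brownian time tau_B = 3 pi eta sigma^3 / k_BT; diffusion-limited on-rate
#' k_on = 4 pi (D_1 + D_2)(a_1 + a_2) with D_1 = k_BT/(3 pi eta a_1);
#' K_d = k_off / k_on. `reported` mirrors one-significant-figure arithmetic
#' (each derived quantity uses the rounded value of its inputs, so e.g.
#' tau_B = 40 ns gives k_off = 250 1/s and K_d = 50 nM); `raw` carries the
#' unrounded values. Both conventions for the chain relaxation time
#' (R_g^2/D and R_g^2/2D) are exposed.
#'
#' @param sigma_nm bead size in nm
#' @param eta_cP solvent viscosity in centipoise
#' @param temperature_K absolute temperature
#' @param k_off_sim unbinding rate in 1/tau_B
#' @param a1_nm,a2_nm protein and target sizes for the Smoluchowski rate
#' @param D2_um2_s diffusion coefficient of the second species (um^2/s)
#' @param k_on_printed the diffusion-controlled on-rate as conventionally
#'   quoted, 5e9 1/M/s (the Smoluchowski formula with these inputs gives
#'   4.2e9; the quoted estimate rounds it up to one generous significant
#'   figure, and the `reported` K_d uses it). Set NULL to round the raw
#'   formula value instead.
#' @param Rg_um,D_um2_s radius of gyration and centre-of-mass diffusion used
#'   for the chain relaxation time estimate
#' @return list with `raw` and `reported` sublists (tau_B_ns, k_on_M_s,
#'   k_off_s, K_d_nM, tau_R_s, tau_R_halfD_s)
#' @export
physical_units <- function(sigma_nm = 2.5, eta_cP = 1, temperature_K = 298,
                           k_off_sim = 1e-5, a1_nm = 40, a2_nm = 10,
                           D2_um2_s = 0, k_on_printed = 5e9,
                           Rg_um = 2, D_um2_s = 0.1) {
  stopifnot(sigma_nm > 0, eta_cP > 0, temperature_K > 0)
  kB <- 1.380649e-23
  kT <- kB * temperature_K
  eta <- eta_cP * 1e-3                       # Pa s
  sig <- sigma_nm * 1e-9
  tau_B <- 3 * pi * eta * sig^3 / kT         # s
  D1 <- kT / (3 * pi * eta * a1_nm * 1e-9)   # m^2/s
  k_on_m3 <- 4 * pi * (D1 + D2_um2_s * 1e-12) * (a1_nm + a2_nm) * 1e-9
  k_on <- k_on_m3 * 6.02214076e23 * 1e3      # M^-1 s^-1
  k_off <- k_off_sim / tau_B
  raw <- list(tau_B_ns = tau_B * 1e9,
              D1_um2_s = D1 * 1e12,
              k_on_M_s = k_on,
              k_off_s = k_off,
              K_d_nM = k_off / k_on * 1e9,
              tau_R_s = (Rg_um)^2 / D_um2_s,
              tau_R_halfD_s = (Rg_um)^2 / (2 * D_um2_s))
  tau_B_1 <- signif(tau_B, 1)
  k_on_1 <- if (is.null(k_on_printed)) signif(k_on, 1) else k_on_printed
  k_off_rep <- k_off_sim / tau_B_1
  reported <- list(tau_B_ns = tau_B_1 * 1e9,
                   k_on_M_s = k_on_1,
                   k_off_s = k_off_rep,
                   K_d_nM = signif(k_off_rep / k_on_1 * 1e9, 1),
                   tau_R_s = raw$tau_R_s,
                   tau_R_halfD_s = raw$tau_R_halfD_s)
  list(raw = raw, reported = reported)
}

#' First unknotting times
#'
#' Per replica, the first sampled time at which the determinant equals 1;
#' replicas that never unknot within the trace are reported as censored.
#'
#' @param traces list of topology traces that begin knotted
#' @return list(times data frame (replica, time, censored), mean, sd,
#'   quantiles of the uncensored times, n_censored)
#' @export
first_unknotting_times <- function(traces) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (tr$det[1] == 1) stop("trace ", i, " does not begin knotted")
    j <- which(tr$det == 1)[1]
    if (is.na(j))
      data.frame(replica = i, time = tr$time[nrow(tr)], censored = TRUE)
    else
      data.frame(replica = i, time = tr$time[j], censored = FALSE)
  })
  df <- do.call(rbind, rows)
  obs <- df$time[!df$censored]
  list(times = df,
       mean = if (length(obs)) mean(obs) else NA_real_,
       sd = if (length(obs) > 1) sd(obs) else NA_real_,
       quantiles = if (length(obs)) quantile(obs, c(.25, .5, .75)) else NULL,
       n_censored = sum(df$censored))
}
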