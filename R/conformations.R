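#' Ring conformation
#'
#' A closed bead-spring ring: an N x 3 matrix of bead positions with implicit
#' bonds between consecutive rows and between the last and first row.
#'
#' @param coords numeric N x 3 matrix of positions (units of sigma)
#' @param params optional [sim_params()]; if given, all bond lengths are
#'   checked against the FENE domain (`r < R0`)
#' @return the matrix with class `ring_conformation`
#' @export
ring_conformation <- function(coords, params = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3 || nrow(coords) < 3)
    stop("a ring conformation needs an N x 3 coordinate matrix with N >= 3")
  if (anyNA(coords)) stop("ring conformation contains NA coordinates")
  if (!is.null(params)) {
    bl <- bond_lengths(coords)
    bad <- which(bl >= params$R0)
    if (length(bad))
      stop("bond(s) outside the FENE domain at bead index ", bad[1])
  }
  structure(coords, class = c("ring_conformation", "matrix", "array"))
}

bond_lengths <- function(coords) {
  nxt <- coords[c(2:nrow(coords), 1), , drop = FALSE]
  sqrt(rowSums((nxt - coords)^2))
}

#' Parametric (2,q) torus-knot ring
#'
#' Samples the standard (2,q) torus curve at N points equally spaced in arc
#' length, then rescales so the mean bond length equals `sigma`. For odd q
#' this is the (2,q) torus knot whose knot determinant is q (q = 1 gives the
#' unknot); q = 5 is the 5_1 initial substrate used throughout.
#'
#' @param N number of beads (must be at least 20 q)
#' @param q odd torus-knot parameter, typically 1, 3, 5 or 7
#' @param sigma target mean bond length
#' @param R,r major and minor radius of the supporting torus (only their
#'   ratio matters; the curve is rescaled)
#' @param verify check the resulting topology with [alexander_det()] and
#'   abort on mismatch (default TRUE)
#' @return a [ring_conformation()]
#' @export
#' @examples
#' ring <- make_torus_knot(200, q = 3)
#' alexander_det(ring)  # 3
make_torus_knot <- function(N, q, sigma = 1, R = 2, r = 1, verify = TRUE) {
  stopifnot(q %% 2 == 1, q >= 1, N >= 20 * q)
  n_dense <- 200L * N
  phi <- seq(0, 2 * pi, length.out = n_dense + 1L)[-(n_dense + 1L)]
  pts <- cbind((R + r * cos(q * phi)) * cos(2 * phi),
               (R + r * cos(q * phi)) * sin(2 * phi),
               r * sin(q * phi))
  seg <- sqrt(rowSums((pts[c(2:n_dense, 1), ] - pts)^2))
  s <- cumsum(c(0, seg[-n_dense]))
  target <- seq(0, sum(seg), length.out = N + 1L)[1:N]
  conf <- pts[findInterval(target, s), , drop = FALSE]
  conf <- conf * sigma / mean(bond_lengths(conf))
  conf <- ring_conformation(conf)
  if (verify) {
    d <- alexander_det(conf)
    if (d != q)
      stop("torus-knot fixture failed its topology check: expected ", q,
           ", got ", d)
  }
  conf
}

#' Radius of gyration
#'
#' Mass-weighted radius of gyration with equal bead masses, per conformation
#' or per trajectory frame.
#'
#' @param x a [ring_conformation()], a plain N x 3 matrix, or a trajectory
#'   returned by [langevin_run()] / [simulate_topo2()]
#' @return a scalar, or a numeric vector (one value per frame)
#' @export
radius_of_gyration <- function(x) {
  rg1 <- function(m) {
    ctr <- colMeans(m)
    sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
  }
  if (inherits(x, "kr_trajectory")) {
    nf <- dim(x$frames)[3]
    vapply(seq_len(nf), function(i) rg1(x$frames[, , i]), numeric(1))
  } else {
    rg1(as.matrix(x))
  }
}

#' Extract one frame of a trajectory as a ring conformation
#'
#' @param traj a trajectory from [langevin_run()] or [simulate_topo2()]
#' @param i frame index (default: last frame)
#' @export
trajectory_frame <- function(traj, i = dim(traj$frames)[3]) {
  ring_conformation(traj$frames[, , i])
}
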