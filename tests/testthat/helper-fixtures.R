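# Geometric fixtures built in code; nothing is stored on disk.

# planar circle with unit-ish bonds
circle_ring <- function(N, radius = N / (2 * pi)) {
  th <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
  ring_conformation(cbind(radius * cos(th), radius * sin(th), 0))
}

# circle with a tight 5-bead hairpin excursion replacing beads around `at`
hairpin_ring <- function(N = 60, at = 20) {
  x <- as.matrix(circle_ring(N))
  ctr <- x[at, ]
  nrm <- ctr / sqrt(sum(ctr^2))
  # out-and-back spike of ~2 sigma, sharp turns at the apex
  x[at - 2, ] <- ctr + 0.8 * nrm + c(0, 0, 0.3)
  x[at - 1, ] <- ctr + 1.6 * nrm + c(0, 0, 0.5)
  x[at, ]     <- ctr + 2.2 * nrm
  x[at + 1, ] <- ctr + 1.6 * nrm - c(0, 0, 0.5)
  x[at + 2, ] <- ctr + 0.8 * nrm - c(0, 0, 0.3)
  ring_conformation(x)
}

# extended ring with one compact cluster: beads `cl` folded into a ball
clustered_ring <- function(N = 120, cl = 30:59) {
  x <- as.matrix(circle_ring(N, radius = N / (2 * pi)))
  ctr <- colMeans(x[cl, ])
  set.seed(4)
  x[cl, ] <- matrix(rep(ctr, each = length(cl)), ncol = 3) +
    matrix(runif(3 * length(cl), -1.2, 1.2), ncol = 3)
  ring_conformation(x)
}

# tight open trefoil (n_knot beads) spliced into a tall "staple" detour of
# n_loop beads rising far above the knot; ground truth: the knotted arc is
# the first n_knot beads
spliced_trefoil_ring <- function(n_knot = 30, n_loop = 270) {
  t <- pi + seq(0, 2 * pi, length.out = n_knot + 1)[1:n_knot]
  kn <- cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t))
  kn <- kn / mean(sqrt(rowSums((kn[c(2:n_knot, 1), ] - kn)^2)))  # bonds ~ 1
  a <- kn[n_knot, ]; b <- kn[1, ]          # gap at the outermost rim point
  H <- 30
  p1 <- a + c(0, 0, H); p2 <- b + c(0, 0, H)
  seg <- c(H, sqrt(sum((p2 - p1)^2)), H)
  n_pts <- pmax(2, round(n_loop * seg / sum(seg)))
  lerp <- function(u, v, n) t(vapply(seq_len(n), function(i)
    u + (v - u) * i / (n + 1), numeric(3)))
  ring_conformation(rbind(kn, lerp(a, p1, n_pts[1]), lerp(p1, p2, n_pts[2]),
                          lerp(p2, b, n_pts[3])))
}

# brute-force Eq-5 window curvature argmax (independent oracle)
brute_max_curvature <- function(x, l_T) {
  x <- as.matrix(x); N <- nrow(x)
  tv <- x[c(2:N, 1), ] - x
  best <- -Inf; besti <- 1L
  for (i in 1:N) {
    s <- 0
    for (j in (-l_T %/% 2):(l_T %/% 2)) {
      k1 <- ((i - 1 + j) %% N) + 1
      k2 <- ((i + j) %% N) + 1
      s <- s + 1 - sum(tv[k1, ] * tv[k2, ]) /
        (sqrt(sum(tv[k1, ]^2)) * sqrt(sum(tv[k2, ]^2)))
    }
    if (s > best + 1e-12) { best <- s; besti <- i }
  }
  besti
}

# brute-force Eq-6 density argmax (independent oracle)
brute_max_density <- function(x, R) {
  x <- as.matrix(x); N <- nrow(x)
  counts <- vapply(1:N, function(i)
    sum(sqrt(colSums((t(x) - x[i, ])^2)) < R), integer(1))
  which.max(counts)
}

random_rotation <- function() {
  th <- runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                 0, sin(th[2]), cos(th[2])), 3, 3)
  Rz %*% Rx
}
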