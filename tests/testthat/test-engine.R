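test_that("identical seeds give bitwise-identical trajectories", {
  ring <- make_torus_knot(60, 1, verify = FALSE)
  p <- sim_params(N = 60, lp = 5, seed = 42)
  t1 <- langevin_run(ring, p, 2000, sample_every = 200)
  t2 <- langevin_run(ring, p, 2000, sample_every = 200)
  expect_identical(t1$frames, t2$frames)
  t3 <- langevin_run(ring, p, 2000, sample_every = 200, seed = 43)
  expect_false(identical(t3$frames, t2$frames))
})

test_that("NVE limit (zero noise, zero friction) conserves energy", {
  # secular drift measured between the first and last deciles; the bounded
  # symplectic oscillation scales as dt^2 and is excluded by the averaging
  ring <- make_torus_knot(50, 1, verify = FALSE)
  p <- sim_params(N = 50, lp = 20, dt = 5e-4, gamma = 0, temperature = 0)
  set.seed(5)
  v0 <- matrix(rnorm(150, 0, 0.3), 50, 3)
  tr <- langevin_run(ring, p, n_steps = 1e4, sample_every = 10, v0 = v0)
  E <- rowSums(tr$energies)
  n <- length(E)
  drift <- abs(mean(E[(n - 100):n]) - mean(E[1:100]))
  expect_lt(drift, 1e-4)
})

test_that("damped zero-temperature dynamics relaxes and then stays put", {
  ring <- make_torus_knot(40, 1, verify = FALSE)
  p <- sim_params(N = 40, lp = 10, dt = 0.01, gamma = 1, temperature = 0)
  v0 <- matrix(0, 40, 3)
  tr <- langevin_run(ring, p, 5000, sample_every = 100, v0 = v0)
  E <- rowSums(tr$energies)                   # potential + kinetic
  expect_true(all(diff(E) < 1e-6))            # dissipative: monotone descent
  expect_lt(E[length(E)], E[1])
  # the descent stalls as the minimum is approached
  expect_lt(abs(E[51] - E[41]), abs(E[11] - E[1]))
})

test_that("equipartition holds within 3% in the underdamped thermostat", {
  ring <- make_torus_knot(100, 1, verify = FALSE)
  p <- sim_params(N = 100, lp = 10, dt = 0.005, seed = 7)
  tr <- langevin_run(ring, p, 6e4, sample_every = 200)
  ke <- tr$energies[-(1:50), "kinetic"] / (3 * 100)
  expect_lt(abs(mean(ke) - 0.5) / 0.5, 0.03)
})

test_that("equilibrium bond length matches the bonded-potential minimum", {
  # the FENE + truncated-shifted-LJ minimum sits near 0.965 sigma; the
  # independently optimised minimum is the oracle for the engine's mean
  p <- sim_params(N = 100, lp = 10, seed = 7)
  ub <- function(r) -0.5 * p$K_fene * p$R0^2 * log(1 - (r / p$R0)^2) +
    pair_energy(r, "LJ", p)
  rmin <- optimize(ub, c(0.8, 1.1))$minimum
  ring <- make_torus_knot(100, 1, verify = FALSE)
  tr <- langevin_run(ring, p, 5e4, sample_every = 500)
  bl <- vapply(30:101, function(i)
    mean(knotrelax:::bond_lengths(tr$frames[, , i])), numeric(1))
  expect_lt(abs(mean(bl) - rmin) / rmin, 0.02)
})

test_that("tangent correlations recover the persistence length within 15%", {
  N <- 200
  p <- sim_params(N = N, lp = 10, seed = 11)
  ring <- make_torus_knot(N, 1, verify = FALSE)
  eq <- langevin_run(ring, p, 5e4, sample_every = 5e4)
  tr <- langevin_run(eq$x_final, p, 2e5, sample_every = 2e3, seed = 12)
  nf <- dim(tr$frames)[3]
  smax <- 8
  corr <- matrix(0, nf - 9, smax)
  for (w in seq_len(nf - 9)) {
    m <- tr$frames[, , w + 9]
    b <- m[c(2:N, 1), ] - m
    bn <- b / sqrt(rowSums(b^2))
    for (s in seq_len(smax))
      corr[w, s] <- mean(rowSums(bn * bn[c((1 + s):N, 1:s), ]))
  }
  cc <- colMeans(corr)
  lp_fit <- -1 / coef(lm(log(cc) ~ seq_len(smax)))[[2]]
  expect_lt(abs(lp_fit - p$lp) / p$lp, 0.15)
})

test_that("topology is frozen without a soft segment", {
  ring <- make_torus_knot(100, 3)
  p <- sim_params(N = 100, lp = 20, seed = 3)
  tr <- langevin_run(ring, p, 1e5, sample_every = 2e4, l_T = 0)
  for (i in seq_len(dim(tr$frames)[3]))
    expect_identical(alexander_det(tr$frames[, , i]), 3)
})

test_that("a soft segment at A = 2 kT does allow strand crossings", {
  ring <- make_torus_knot(100, 3)
  p <- sim_params(N = 100, lp = 5, seed = 1)
  ring <- equilibrate_fixed_topology(ring, p, 2e4, seed = 21)
  crossed <- FALSE
  for (s in 1:4) {            # small ensemble; crossing is stochastic
    tr <- langevin_run(ring, p, 2e5, sample_every = 1e4,
                       soft_start = 25 * s, l_T = 25, seed = 100 + s)
    dets <- vapply(seq_len(dim(tr$frames)[3]),
                   function(i) alexander_det(tr$frames[, , i]), numeric(1))
    if (any(dets != 3)) { crossed <- TRUE; break }
  }
  expect_true(crossed)
})

test_that("FENE violations and instabilities abort with a diagnostic", {
  bad <- cbind(c(0, 2, 1), c(0, 0, 1), 0)  # bond of length 2 > R0
  p <- sim_params(N = 3, lp = 1)
  expect_error(langevin_run(bad, p, 10, 10), "FENE domain violation")
  expect_error(ring_conformation(bad, p), "FENE domain")
})

test_that("equilibrate_fixed_topology is the identity at 0 steps and preserves knots", {
  tre <- make_torus_knot(100, 3)
  p <- sim_params(N = 100, lp = 20, seed = 2)
  same <- equilibrate_fixed_topology(tre, p, 0)
  expect_equal(as.matrix(same), as.matrix(tre), ignore_attr = TRUE)
  eq <- equilibrate_fixed_topology(tre, p, 1e4, seed = 3)
  expect_identical(attr(eq, "det"), 3)
})

test_that("equilibration thermalises: the energy trace settles", {
  # from the parametric fixture the potential energy first drifts down, then
  # fluctuates about equilibrium: late-window variability < early-window
  tre <- make_torus_knot(100, 3)
  p <- sim_params(N = 100, lp = 10, seed = 9)
  tr <- langevin_run(tre, p, 3e4, sample_every = 300, l_T = 0)
  U <- rowSums(tr$energies[, c("pair", "fene", "bend")])
  n <- length(U)
  expect_lt(sd(U[(n - 20):n]), sd(U[1:21]))
})

test_that("torus-knot fixtures have near-uniform bonds of length sigma", {
  for (q in c(1, 5)) {
    ring <- make_torus_knot(60 * max(q, 2), q, verify = FALSE)
    bl <- knotrelax:::bond_lengths(ring)
    expect_equal(mean(bl), 1, tolerance = 1e-6)
    expect_lt(max(abs(bl - 1)), 0.1)   # all bonds within 10% of sigma
  }
})
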