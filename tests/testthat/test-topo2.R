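test_that("topo2_state enforces mode/rate consistency", {
  expect_error(topo2_state(mode = "static", k_j = 1), "static")
  expect_error(topo2_state(mode = "jump"), "k_j > 0")
  expect_error(topo2_state(mode = "diffuse"), "k_d > 0")
  s <- topo2_state(5, 50, "jump", k_j = 0.01)
  expect_s3_class(s, "topo2_state")
  expect_identical(s$ramp_state, "bound")
})

test_that("max-curvature selection matches brute force and finds hairpins", {
  expect_identical(select_max_curvature(circle_ring(60), 10), 1L)  # tie-break
  hp <- hairpin_ring(60, at = 20)
  i <- select_max_curvature(hp, 10)
  expect_identical(i, brute_max_curvature(hp, 10))
  expect_lt(min(abs(i - 20), 60 - abs(i - 20)), 5 + 1)  # near the apex
  # invariance under rigid motion
  set.seed(3)
  M <- as.matrix(hp) %*% random_rotation() + 2
  expect_identical(select_max_curvature(M, 10), i)
  # random conformations against the oracle
  for (k in 1:5) {
    set.seed(k)
    x <- as.matrix(circle_ring(40)) + matrix(rnorm(120, 0, 0.3), 40, 3)
    expect_identical(select_max_curvature(x, 8), brute_max_curvature(x, 8))
  }
})

test_that("max-density selection matches brute force and finds clusters", {
  expect_identical(select_max_density(circle_ring(30), 1000), 1L)  # all equal
  cl <- clustered_ring(120, 30:59)
  i <- select_max_density(cl, 3)
  expect_identical(i, brute_max_density(cl, 3))
  expect_true(i %in% 30:59)
  expect_identical(select_max_density(cl, 1e-9), 1L)  # R -> 0+: all counts 1
  for (k in 1:5) {
    set.seed(10 + k)
    x <- as.matrix(circle_ring(50)) + matrix(rnorm(150, 0, 0.5), 50, 3)
    expect_identical(select_max_density(x, 2.5), brute_max_density(x, 2.5))
  }
})

test_that("static binding never relocates", {
  topo <- topo2_state(7, 10, "static")
  up <- update_binding(topo, circle_ring(60), 1e5)
  expect_identical(up$state$start_index, 7L)
  expect_identical(nrow(up$events), 0L)
})

test_that("random jumps land uniformly over the ring", {
  topo <- topo2_state(1, 50, "jump", k_j = 1e-2)
  set.seed(8)
  up <- update_binding(topo, circle_ring(500), 1e6)
  expect_gt(nrow(up$events), 5000)
  expect_true(all(diff(up$events$time) > 0))  # strictly increasing log
  h <- tabulate(up$events$new_index, 500)
  pval <- suppressWarnings(chisq.test(h)$p.value)
  expect_gt(pval, 0.01)
})

test_that("curvilinear diffusion has D = 0.5 k_d sigma^2", {
  # mean squared index displacement after time t must be ~ 2 D t = t
  set.seed(12)
  conf <- matrix(0, 10000, 3)  # large ring so the walk never wraps
  t_end <- 400
  disp <- replicate(300, {
    topo <- topo2_state(5000, 50, "diffuse", k_d = 1)
    up <- update_binding(topo, conf, t_end)
    up$state$start_index - 5000
  })
  msd <- mean(disp^2)
  expect_lt(abs(msd - t_end) / t_end, 0.2)
})

test_that("unbind_ramp schedules A_unbind then rebinding, and pair energies scale", {
  p <- sim_params(N = 100)
  topo <- topo2_state(1, 50, "jump", k_j = 1e-2)
  r <- unbind_ramp(topo, p)
  expect_identical(r$state$ramp_state, "ramping")
  expect_equal(r$schedule$amplitude, c(20, 2))
  expect_identical(r$schedule$duration_steps[1], topo$ramp_duration)
  # contact energy rises from 2 A_soft to 2 A_unbind during the ramp
  expect_equal(pair_energy(0, "soft", p, A = p$A_soft), 4)
  expect_equal(pair_energy(0, "soft", p, A = p$A_unbind), 40)
})

test_that("the engine keeps exactly one soft segment and logs orderly events", {
  ring <- make_torus_knot(80, 1, verify = FALSE)
  p <- sim_params(N = 80, lp = 5, seed = 4)
  topo <- topo2_state(11, 16, "jump", k_j = 0.05, ramp_duration = 50)
  tr <- simulate_topo2(ring, p, topo, 4e4, sample_every = 500)
  expect_gt(nrow(tr$events), 2)
  expect_true(all(diff(tr$events$time) > 0))
  expect_true(all(tr$events$new_index %in% 1:80))
  # per-frame amplitude is either bound (A_soft) or ramping (A_unbind)
  expect_true(all(tr$amplitude %in% c(p$A_soft, p$A_unbind)))
  # the segment location tracked per frame follows the event log
  expect_true(all(tr$seg_start %in% 1:80))
  # static mode: empty log, fixed segment
  tr0 <- simulate_topo2(ring, p, topo2_state(11, 16, "static"), 1e4, 500)
  expect_identical(nrow(tr0$events), 0L)
  expect_true(all(tr0$seg_start == 11))
})

test_that("diffusive mode slides one bead at a time in the engine", {
  ring <- make_torus_knot(80, 1, verify = FALSE)
  p <- sim_params(N = 80, lp = 5, seed = 4)
  topo <- topo2_state(40, 16, "diffuse", k_d = 0.5)
  tr <- simulate_topo2(ring, p, topo, 2e4, sample_every = 2e3)
  expect_gt(nrow(tr$events), 50)
  jumps <- (tr$events$new_index - tr$events$old_index) %% 80
  expect_true(all(jumps %in% c(1, 79)))
})
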