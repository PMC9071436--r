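mk_trace <- function(det, time = seq_along(det) - 1, replica = 1L) {
  structure(data.frame(time = time, det = det, replica = replica),
            class = c("topology_trace", "data.frame"))
}

test_that("knotting probability counts knotted replicas and validates blocking", {
  tr <- list(mk_trace(c(3, 3)), mk_trace(c(3, 1)), mk_trace(c(5, 1)),
             mk_trace(c(3, 3)))
  pk <- knotting_probability(tr, n_blocks = 2)
  expect_equal(pk$P_K, c(1, 0.5))
  expect_error(knotting_probability(tr[1:2], n_blocks = 4), "fewer replicas")
  # all unknotted: P_K and sem identically zero
  tr0 <- replicate(4, mk_trace(c(1, 1)), simplify = FALSE)
  pk0 <- knotting_probability(tr0, n_blocks = 2)
  expect_true(all(pk0$P_K == 0) && all(pk0$sem == 0))
})

test_that("merged replica sets give the replica-weighted mean curve", {
  set.seed(1)
  mk <- function(n) replicate(n, mk_trace(sample(c(1, 3), 6, replace = TRUE)),
                              simplify = FALSE)
  a <- mk(8); b <- mk(16)
  pa <- knotting_probability(a, 4)$P_K
  pb <- knotting_probability(b, 4)$P_K
  pm <- knotting_probability(c(a, b), 4)$P_K
  expect_equal(pm, (8 * pa + 16 * pb) / 24)
})

test_that("blocking SEM agrees with the binomial closed form", {
  # 64 iid Bernoulli(0.5) replicas, 8 blocks; median over seeds within 30%
  target <- sqrt(0.25 / 64)
  sems <- vapply(1:40, function(s) {
    set.seed(s)
    tr <- lapply(1:64, function(i) mk_trace(ifelse(runif(2) < 0.5, 3, 1)))
    knotting_probability(tr, 8, seed = s)$sem[1]
  }, numeric(1))
  expect_lt(abs(median(sems) - target) / target, 0.3)
})

test_that("topology change rate counts flips per unit time", {
  expect_equal(topology_change_rate(mk_trace(c(3, 3, 3, 3))), 0)
  expect_equal(topology_change_rate(mk_trace(c(5, 3, 5, 3, 1),
                                             time = c(0, 1, 2, 3, 4))), 1)
  # downsampling never increases the count
  set.seed(2)
  tr <- mk_trace(sample(c(1, 3, 5), 101, replace = TRUE), time = 0:100)
  half <- tr[seq(1, 101, 2), ]
  n_full <- sum(diff(tr$det) != 0)
  n_half <- sum(diff(half$det) != 0)
  expect_lte(n_half, n_full)
})

test_that("max_alexander follows the first departure convention", {
  expect_equal(max_alexander(mk_trace(c(5, 5, 3, 7, 1))), 7)
  expect_equal(max_alexander(mk_trace(c(5, 3, 1, 1))), 3)
  expect_equal(max_alexander(mk_trace(c(5, 5, 5))), 1)   # never departs
  # ensemble mean equals direct enumeration
  set.seed(5)
  traces <- replicate(50, mk_trace(c(5, sample(c(1, 3, 5, 7), 9, TRUE))),
                      simplify = FALSE)
  direct <- vapply(traces, function(tr) {
    i0 <- which(tr$det != 5)[1]
    if (is.na(i0)) 1 else max(tr$det[i0:nrow(tr)])
  }, numeric(1))
  expect_equal(vapply(traces, max_alexander, numeric(1)), direct)
})

test_that("fit_decay recovers exponentials (criterion 5 backing)", {
  t <- seq(0, 500, by = 5)
  clean <- data.frame(time = t, P_K = exp(-t / 100))
  expect_lt(abs(fit_decay(clean)$tau - 100) / 100, 1e-3)
  # noisy recovery: median over 50 seeds within 10%
  taus <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- data.frame(time = t,
                        P_K = pmax(pmin(exp(-t / 100) + rnorm(length(t), 0, 0.02), 1), 0))
    fit_decay(noisy)$tau
  }, numeric(1))
  expect_lt(abs(median(taus) - 100) / 100, 0.10)
  # constant curve: infinity sentinel
  expect_identical(fit_decay(data.frame(time = t, P_K = rep(1, length(t))))$tau, Inf)
})

test_that("scaling predictions expose the N^(2+theta) vs N^(1-theta) split", {
  expect_equal(scaling_predictions(500, 1)$ratio_exponent, 3)
  s1 <- scaling_predictions(500, 0.5)
  s2 <- scaling_predictions(1000, 0.5)
  expect_equal(s2$tau_T_scaling / s1$tau_T_scaling, 2^0.5, tolerance = 1e-12)
  expect_equal(s1$tau_R_exponent, 2.5)
  expect_equal(s2$tau_R_scaling / s1$tau_R_scaling, 2^2.5, tolerance = 0.1)
})

test_that("physical unit mapping reproduces the printed arithmetic", {
  u <- physical_units()
  expect_equal(u$reported$tau_B_ns, 40)      # 3 pi eta sigma^3 / kT, 1 s.f.
  expect_equal(u$reported$k_off_s, 250)      # 1e-5 / 40 ns
  expect_equal(u$reported$K_d_nM, 50)        # 250 / 5e9
  expect_equal(u$reported$k_on_M_s, 5e9)
  # raw values stay in physical range
  expect_true(abs(u$raw$tau_B_ns - 35.8) < 1)
  expect_true(abs(u$raw$D1_um2_s - 10.9) < 0.5)
  # both chain relaxation conventions exposed
  expect_equal(u$raw$tau_R_s, 40)
  expect_equal(u$raw$tau_R_halfD_s, 20)
})

test_that("radius of gyration has its closed forms", {
  expect_equal(radius_of_gyration(matrix(1, 10, 3)), 0)
  expect_equal(radius_of_gyration(circle_ring(400, radius = 7)), 7,
               tolerance = 1e-12)
})

test_that("first unknotting times handle censoring and match a generator", {
  tr <- list(mk_trace(c(3, 3, 1), time = c(0, 150, 300)),
             mk_trace(c(3, 3, 3), time = c(0, 150, 300)))
  fu <- first_unknotting_times(tr)
  expect_equal(fu$times$time[1], 300)
  expect_false(fu$times$censored[1])
  expect_true(fu$times$censored[2])
  expect_equal(fu$n_censored, 1)
  # exponential first-passage ensemble: sample mean within 2 SEM
  set.seed(9)
  mu <- 50
  times <- seq(0, 1000, by = 1)
  traces <- lapply(rexp(400, 1 / mu), function(ft) {
    det <- ifelse(times < ft, 3, 1)
    mk_trace(det, time = times)
  })
  fu <- first_unknotting_times(traces)
  obs <- fu$times$time[!fu$times$censored]
  expect_lt(abs(fu$mean - mu), 2 * sd(obs) / sqrt(length(obs)) + 1)  # +1: grid
})
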