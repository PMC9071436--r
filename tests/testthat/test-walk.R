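lay <- build_layout()

test_that("the default layout is an overlapping unknot-3_1-5_1 chain", {
  d <- lay$disks
  expect_identical(d$label[which.max(d$r)], "unknot")
  # every adjacent pair overlaps with positive lens area
  for (i in 1:2) {
    gap <- abs(d$cx[i + 1] - d$cx[i])
    expect_lt(gap, d$r[i] + d$r[i + 1])
    expect_gt(d$r[i] + d$r[i + 1] - gap, 0)
  }
  expect_error(build_layout(c(unknot = 4, "3_1" = 2), overlap = 0),
               "overlap")
  expect_error(build_layout(c(a = 4, b = 2)), "unknot")
})

test_that("free diffusion shows MSD = 2 d D n dt (d = 2)", {
  huge <- build_layout(c(unknot = 1e4, "5_1" = 1e4), overlap = 0.5)
  set.seed(21)
  n <- 400; steps <- 500; dt <- 1e-3; D <- 0.5
  px <- rep(huge$disks$cx[2], n); py <- rep(0, n)
  x0 <- px; y0 <- py
  disk <- rep(2L, n)
  for (s in 1:steps) {
    st <- knotrelax:::walk_step_n(px, py, disk, huge, dt, D, 0, "i")
    px <- st$x; py <- st$y; disk <- st$disk
  }
  msd <- mean((px - x0)^2 + (py - y0)^2)
  expect_lt(abs(msd - 4 * D * steps * dt) / (4 * D * steps * dt), 0.15)
})

test_that("teleport kernels have the right support", {
  set.seed(31)
  k <- 3  # the 5_1 disk
  d <- lay$disks
  tp <- knotrelax:::sample_kernel(lay, k, 500, "iii")
  rad <- sqrt((tp$x - d$cx[k])^2 + (tp$y - d$cy[k])^2)
  expect_true(all(rad <= d$r[k] + 1e-12))
  expect_true(all(rad >= d$r[k] * (1 - lay$annulus_width) - 1e-12))
  tp <- knotrelax:::sample_kernel(lay, k, 500, "iv")
  rad <- sqrt((tp$x - d$cx[k])^2 + (tp$y - d$cy[k])^2)
  expect_true(all(rad <= d$r[k] + 1e-12))
  # strip faces the lower-complexity neighbour (toward smaller x)
  expect_true(all(tp$x <= d$cx[k] - d$r[k] + lay$strip_width * d$r[k] + 1e-12))
  tp <- knotrelax:::sample_kernel(lay, k, 2000, "ii")
  rad2 <- (tp$x - d$cx[k])^2 + (tp$y - d$cy[k])^2
  # uniform over the disk: radial shells of equal area are equally occupied
  shells <- cut(rad2 / d$r[k]^2, seq(0, 1, 0.1))
  pval <- suppressWarnings(chisq.test(table(shells))$p.value)
  expect_gt(pval, 0.01)
})

test_that("walkers never leave the union of disks and labels stay valid", {
  set.seed(41)
  w <- walker_state(c(lay$disks$cx[3], 0), lay, model = "iii",
                    jump_rate = 300)
  for (s in 1:400) {
    w <- step_walker(w, lay, 1e-3)
    expect_false(is.na(w$disk))
  }
  expect_true(w$label %in% lay$disks$label)
})

test_that("a single walker's trajectory can be recorded", {
  res <- run_ensemble(lay, "iii", n_walkers = 20, horizon = 0.2,
                      record_walker = 3, seed = 2)
  expect_identical(nrow(res$path), 201L)
  expect_true(all(res$path$label %in% lay$disks$label))
  expect_false(anyNA(res$path$x))
})

test_that("with jump_rate = 0 models ii-iv reduce to model i exactly", {
  res_i <- run_ensemble(lay, "i", n_walkers = 50, horizon = 0.5, seed = 77)
  for (m in c("ii", "iii", "iv")) {
    res_m <- run_ensemble(lay, m, n_walkers = 50, horizon = 0.5,
                          jump_rate = 0, seed = 77)
    expect_identical(res_m$curve$P_K, res_i$curve$P_K)
  }
})

test_that("P_K(0) = 1 from the 5_1 centre and decay ordering i > ii > iii > iv", {
  taus <- vapply(c("i", "ii", "iii", "iv"), function(m) {
    res <- run_ensemble(lay, m, n_walkers = 400, horizon = 12, seed = 5)
    expect_equal(res$curve$P_K[1], 1)
    res$tau
  }, numeric(1))
  expect_true(taus[["i"]] > taus[["ii"]],
              label = sprintf("tau_i (%.2f) > tau_ii (%.2f)", taus[["i"]], taus[["ii"]]))
  expect_true(taus[["ii"]] > taus[["iii"]],
              label = sprintf("tau_ii (%.2f) > tau_iii (%.2f)", taus[["ii"]], taus[["iii"]]))
  expect_true(taus[["iii"]] > taus[["iv"]],
              label = sprintf("tau_iii (%.2f) > tau_iv (%.2f)", taus[["iii"]], taus[["iv"]]))
})

test_that("models i/ii share equilibrium occupancy; iii/iv break detailed balance", {
  # two disks so plain diffusion equilibrates within the horizon; coarser dt
  # and a moderate jump rate keep the per-step teleport probability < 1
  two <- build_layout(c(unknot = 2, "5_1" = 1))
  occ <- lapply(c("i", "ii", "iii", "iv"), function(m)
    run_ensemble(two, m, n_walkers = 150, horizon = 60, dt = 5e-3,
                 jump_rate = 50, seed = 13)$occupancy)
  names(occ) <- c("i", "ii", "iii", "iv")
  # i and ii agree with each other (both reversible; occupancy ~ area)
  expect_lt(max(abs(occ$i - occ$ii)), 0.08)
  # iii/iv stationary densities are enriched where their kernels resample:
  # track within-disk positions and compare rim / strip occupation with the
  # reversible baseline
  rim_frac <- function(model) {
    set.seed(17)
    d <- two$disks
    px <- rep(d$cx[2], 150); py <- rep(0, 150); disk <- rep(2L, 150)
    hits <- 0; tot <- 0
    for (s in 1:6000) {
      st <- knotrelax:::walk_step_n(px, py, disk, two, 5e-3, 0.5, 50, model)
      px <- st$x; py <- st$y; disk <- st$disk
      if (s > 3000) {
        # conditional on the 5_1 disk: in the unknot disk model iv has no
        # lower-complexity neighbour and falls back to uniform jumps
        sel <- disk == 2L
        rho <- sqrt((px[sel] - d$cx[2])^2 + (py[sel] - d$cy[2])^2) / d$r[2]
        hits <- hits + sum(rho > 0.9)
        tot <- tot + length(rho)
      }
    }
    hits / tot
  }
  base <- rim_frac("i")         # ~ area share of the outer 10% shell (0.19)
  expect_gt(rim_frac("iii"), base + 0.1)
  expect_gt(rim_frac("iv"), base + 0.05)
})
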