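test_that("state functions partition fate and respect their limits", {
  set.seed(1)
  g <- c(0, runif(200, 0, 10)); t <- c(0, runif(200, 0, 4))
  sd_ <- stateDeath(g, t, gmin = 0.1)
  sp_ <- stateProlif(g, t, gmin = 0.1)
  expect_equal(sd_ + sp_, rep(1, length(g)), tolerance = 1e-15)
  expect_true(all(sd_ >= 0 & sd_ < 1))
  expect_true(all(sp_ > 0 & sp_ <= 1))

  # no glucose response at medium change, for any concentration
  expect_identical(stateDeath(c(0, 0.1, 1, 10), time = 0, gmin = 0.1),
                   rep(0, 4))
  # direct evaluation at G = Gmin
  expect_equal(stateDeath(0.1, 2, gmin = 0.1), 0.5 * tanh(2), tolerance = 1e-12)
  # limits: starved forever vs glucose-saturated
  expect_equal(stateDeath(0, 50, gmin = 0.1), 1, tolerance = 1e-12)
  expect_equal(stateProlif(1e9, 3, gmin = 0.1), 1, tolerance = 1e-6)

  # monotone: decreasing in glucose at fixed time, increasing in time
  gg <- seq(0, 10, length.out = 50)
  expect_true(all(diff(stateDeath(gg, 2, 0.1)) <= 0))
  tt <- seq(0, 4, length.out = 50)
  expect_true(all(diff(stateDeath(0.5, tt, 0.1)) >= 0))

  expect_error(stateDeath(-1, 1, 0.1), "glucose")
  expect_error(stateDeath(1, -1, 0.1), "glucose >= 0")
  expect_error(stateDeath(1, 1, 0), "gmin")
})

test_that("growthRates reproduces the hand-evaluated equations", {
  p <- testParams(kbys = 0.4)
  r <- growthRates(n = 50, d = 0, glucose = 10, time = 1, params = p, variant = 2)
  sd_ <- (1 - 10 / 10.1) * tanh(1)
  expect_equal(r[["dN"]], 0.092 * 50 * 0.5 * (1 - sd_) - 0.13 * 50 * sd_,
               tolerance = 1e-12)
  expect_equal(r[["dG"]], -2.68e-5 * 1000 * 50 * 10 / 11, tolerance = 1e-12)

  # every term carries a factor N
  expect_equal(unname(growthRates(0, 3, 5, 1, p)), c(0, 0, 0))
  # no dead cells: bystander term contributes nothing (variant 1 == 2)
  expect_equal(growthRates(50, 0, 5, 1, p, variant = 2),
               growthRates(50, 0, 5, 1, p, variant = 1))
  # death only transfers mass: dN + dD equals the logistic term
  r2 <- growthRates(40, 10, 0.5, 2, p, variant = 2)
  logistic <- 0.092 * 40 * (1 - 40 / 100) * stateProlif(0.5, 2, 0.1)
  expect_equal(r2[["dN"]] + r2[["dD"]], logistic, tolerance = 1e-12)
  # empty-well bystander fraction defined as 0, not NaN
  expect_false(any(is.nan(growthRates(0, 0, 1, 1, p))))
})

test_that("simulateGrowth honours structural trivia and invariants", {
  # frozen rates: cells constant, glucose still consumed
  p0 <- kineticParams(kp = 0, kd = 0, kbys = 0, v = 2.68e-5)
  tr <- simulateGrowth(30, 1, 2, p0, times = seq(0, 4, 0.25))
  expect_equal(tr$live_pct, rep(30, nrow(tr)), tolerance = 1e-8)
  expect_equal(tr$dead_pct, rep(1, nrow(tr)), tolerance = 1e-8)
  expect_true(all(diff(tr$glucose_mM) < 0))

  # no consumption: glucose exactly flat
  pv0 <- testParams(v = 0)
  trv <- simulateGrowth(30, 1, 2, pv0, times = seq(0, 4, 0.25))
  expect_equal(trv$glucose_mM, rep(2, nrow(trv)), tolerance = 1e-10)

  # non-negativity and glucose monotonicity on a depleting run
  p <- testParams(kbys = 0.6)
  tr2 <- simulateGrowth(50, 0.5, 0.5, p, times = seq(0, 4, 0.125))
  expect_true(all(tr2$live_pct >= 0 & tr2$dead_pct >= 0))
  expect_true(all(diff(tr2$glucose_mM) <= 1e-10))

  expect_error(simulateGrowth(-1, 0, 1, p), ">= 0")
  expect_error(simulateGrowth(30, 0, 1, p, times = c(0, 0, 1)), "increasing")
})

test_that("variant masking matches parameter nulling", {
  p <- testParams(kbys = 0.5)
  tms <- seq(0, 4, 0.125)
  pk0 <- p; pk0@kbys <- 0
  expect_equal(simulateGrowth(40, 0.5, 1, pk0, variant = 2, times = tms),
               simulateGrowth(40, 0.5, 1, p, variant = 1, times = tms),
               tolerance = 1e-10)
  pd0 <- p; pd0@kd <- 0
  expect_equal(simulateGrowth(40, 0.5, 1, pd0, variant = 2, times = tms),
               simulateGrowth(40, 0.5, 1, p, variant = 3, times = tms),
               tolerance = 1e-10)
})

test_that("adaptive solver agrees with a fine-step RK4 oracle", {
  p <- testParams(kbys = 0.8)
  tms <- c(0, 1, 2, 4)
  tr <- simulateGrowth(45, 0.5, 0.8, p, times = tms)
  orc <- rk4Oracle(45, 0.5, 0.8, p, variant = 2, times = tms, dt = 1e-4)
  expect_equal(tr$live_pct, unname(orc[, "live"]), tolerance = 1e-6)
  expect_equal(tr$dead_pct, unname(orc[, "dead"]), tolerance = 1e-6)
  expect_equal(tr$glucose_mM, unname(orc[, "glucose"]), tolerance = 1e-6)
})

test_that("death only moves mass: N + D grows by the proliferation integral", {
  p <- testParams(kbys = 0.5)
  fine <- seq(0, 4, by = 0.005)
  tr <- simulateGrowth(40, 0.5, 1, p, times = fine)
  sp_ <- stateProlif(tr$glucose_mM, tr$time_days, p@gmin)
  integrand <- p@kp * tr$live_pct * (1 - tr$live_pct / p@theta) * sp_
  growth <- sum((integrand[-1] + integrand[-length(integrand)]) / 2 * diff(fine))
  total <- tr$live_pct + tr$dead_pct
  expect_equal(total[length(total)] - total[1], growth, tolerance = 1e-4)
})

test_that("term contributions decompose the live-cell equation", {
  p <- testParams(kbys = 0.5)
  tr <- simulateGrowth(30, 0, 0.5, p, times = seq(0, 4, 0.125))
  tc <- termContributions(tr, p)
  # at t = 0 with no dead cells both death terms vanish
  expect_equal(tc$logistic[1], 1)
  expect_equal(tc$starvation[1], 0)
  expect_equal(tc$bystander[1], 0)
  ok <- !tc$degenerate
  expect_equal(tc$logistic[ok] + tc$starvation[ok] + tc$bystander[ok],
               rep(1, sum(ok)))

  # no bystander rate: that contribution is identically zero
  p1 <- testParams(kbys = 0)
  tr1 <- simulateGrowth(30, 0.5, 1, p1, times = seq(0, 4, 0.125))
  expect_true(all(termContributions(tr1, p1)$bystander == 0))

  # glucose-rich, lightly seeded wells stay growth-dominated
  trh <- simulateGrowth(20, 0.5, 10, p, times = seq(0, 4, 0.125))
  tch <- termContributions(trh, p, atTimes = c(0, 2, 4))
  expect_true(all(tch$logistic > 0.5))

  # an empty well has no rates at all: flagged, not NaN-propagated
  trz <- simulateGrowth(0, 0, 1, p, times = c(0, 1, 2))
  tcz <- termContributions(trz, p, atTimes = c(0, 1, 2))
  expect_true(all(tcz$degenerate))
})

test_that("trajectories round-trip through CSV", {
  p <- testParams()
  tr <- simulateGrowth(30, 0.5, 2, p, times = seq(0, 4, 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrajectory(tr, f)
  expect_equal(readTrajectory(f), tr, tolerance = 1e-12)
})
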