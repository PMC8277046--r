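test_that("initial-state estimation averages the first three timepoints", {
  pair <- list(live = c(10, 12, 14, 20), dead = c(1, 1, 1, 2))
  est <- estimateInitialState(pair)
  expect_equal(est$n0, 12)
  expect_equal(est$d0, 1)
  expect_equal(est$d0_se, 0)
  expect_error(estimateInitialState(list(live = 1:2, dead = 1:2)), ">= 3")

  # on a noise-free simulated pair the estimate stays within one
  # inter-sample increment of the true initial value
  p <- testParams()
  tr <- simulateGrowth(30, 0.5, 2, p, times = seq(0, 4, 0.125))
  est2 <- estimateInitialState(list(live = tr$live_pct, dead = tr$dead_pct))
  expect_lt(abs(est2$n0 - 30), abs(tr$live_pct[2] - tr$live_pct[1]) * 1.01 + 1e-9)
})

test_that("linearized CIs match the closed-form straight-line solution", {
  set.seed(8)
  x <- seq(0, 5, length.out = 24)
  y <- 1.7 + 0.6 * x + rnorm(24, 0, 0.25)
  fit <- lm(y ~ x)
  J <- cbind(intercept = rep(1, 24), slope = x)
  half <- ciLinearized(stats::residuals(fit), J)
  ref <- stats::confint(fit, level = 0.95)
  expect_equal(unname(half[["intercept"]]), unname(diff(ref[1, ]) / 2),
               tolerance = 1e-8)
  expect_equal(unname(half[["slope"]]), unname(diff(ref[2, ]) / 2),
               tolerance = 1e-8)

  # zero residuals: zero-width intervals
  expect_equal(max(ciLinearized(rep(0, 24), J)), 0)

  # collinear design names its degenerate direction
  expect_error(ciLinearized(y, cbind(a = x, b = 2 * x)), "non-identifiable")
})

test_that("CI coverage sits near nominal over repeated noisy fits", {
  curve <- bystanderLaw("curve", kbys0 = 0.71, alpha = 0.98, beta = 0.22)
  cond <- expand.grid(rep = 1:6, g0 = designGlucoseLevels())
  hitA <- hitK <- logical(200)
  for (r in 1:200) {
    s <- generateLawSamples(curve, cond, relNoise = 0.1, seed = 3000 + r)
    f <- fitCurveLaw(s)
    hitA[r] <- abs(f@alpha - 0.98) <= f@ci95[["alpha"]]
    hitK[r] <- abs(f@kbys0 - 0.71) <= f@ci95[["kbys0"]]
  }
  expect_gte(mean(hitA), 0.85); expect_lte(mean(hitA), 0.99)
  expect_gte(mean(hitK), 0.85); expect_lte(mean(hitK), 0.99)
})

test_that("noise-free cohorts are identified to sub-0.1% accuracy", {
  coh <- quietConstKbysCohort()            # 3 glucose levels, kbys = 0.3
  wi <- wellInfo(coh)
  inits <- data.frame(n0 = wi$n0_pct, d0 = wi$d0_pct)
  fit <- fitGlobal(coh, variant = 2,
                   config = calibrationConfig(nStarts = 4, seed = 21),
                   inits = inits)
  truth <- c(kp = 0.092, kd = 0.13, kbys = 0.3, v = 2.68e-5)
  expect_equal(fit@estimates[names(truth)], truth, tolerance = 1e-3)
  expect_lt(fit@rss, 1e-6)
  # and the multistart winner is never beaten by any candidate start
  expect_true(all(fit@info$startRss >= fit@rss - 1e-8, na.rm = TRUE))
})

test_that("local fits recover a single well and respect nesting", {
  coh <- btCohort24()
  pair <- getPair(coh, 17)
  cfg <- function(s) calibrationConfig(nStarts = 4, seed = s)
  f1 <- fitPair(pair, variant = 1, config = cfg(31), computeCI = FALSE)
  f2 <- fitPair(pair, variant = 2, config = cfg(31), computeCI = FALSE)
  f3 <- fitPair(pair, variant = 3, config = cfg(31), computeCI = FALSE)
  tol <- 1e-6 * f2@rss
  # the complete model strictly contains both reduced ones
  expect_lte(f2@rss, f1@rss + tol)
  expect_lte(f2@rss, f3@rss + tol)

  # multistart result is stable across guess seeds
  f2b <- fitPair(pair, variant = 2, config = cfg(77), computeCI = FALSE)
  expect_equal(f2b@rss, f2@rss, tolerance = 1e-6)
})

test_that("a bystander-free pair yields a vanishing kbys under the full model", {
  prof <- quietProfile()
  prof@law <- bystanderLaw("curve", kbys0 = 0, alpha = 1, beta = 0)  # kbys = 0
  coh <- generateCohort(prof, glucose = 0.5, tiers = 45, replicates = 1,
                        seed = 23, n0Jitter = 0)
  pair <- getPair(coh, 1)
  cfg <- calibrationConfig(nStarts = 4, seed = 5)
  f1 <- fitPair(pair, variant = 1, config = cfg, computeCI = FALSE)
  f2 <- fitPair(pair, variant = 2, config = cfg, computeCI = FALSE)
  expect_lt(f2@estimates[["kbys"]], 1e-2)
  expect_equal(f1@rss, f2@rss, tolerance = 1e-2)
})

test_that("mixed calibration recovers shared rates and the kbys field", {
  mf <- btMixed24()
  coh <- btCohort24()
  est <- mf@global@estimates
  # generating values: kp 0.092, kd 0.13, v 2.68e-5
  expect_equal(est[["kp"]], 0.092, tolerance = 0.15)
  expect_equal(est[["kd"]], 0.13, tolerance = 0.35)
  expect_equal(est[["v"]], 2.68e-5, tolerance = 0.6)
  # per-well kbys tracks the generating law draw
  expect_gt(cor(mf@wells$kbys, wellInfo(coh)$true_kbys), 0.9)
  # pooled mixed RSS cannot beat the sum of per-well local optima
  expect_equal(nrow(mf@wells), nWells(coh))
  expect_true(all(mf@wells$ci95 >= 0, na.rm = TRUE))
})

test_that("global fitting of heterogeneous wells is bounded below by local fits", {
  coh <- btCohort24()
  sub <- coh[, c(1, 7, 13, 19)]
  cfg <- calibrationConfig(nStarts = 3, seed = 41)
  g <- fitGlobal(sub, variant = 2, config = cfg)
  localSum <- sum(vapply(seq_len(nWells(sub)), function(j)
    fitPair(getPair(sub, j), variant = 2, config = cfg, computeCI = FALSE)@rss,
    numeric(1)))
  expect_gte(g@rss, localSum - 1e-6 * localSum)
  # a single-well cohort degenerates to the local fit
  one <- coh[, 5]
  gl1 <- fitGlobal(one, variant = 2, config = cfg)
  lo1 <- fitPair(getPair(coh, 5), variant = 2, config = cfg)
  expect_equal(gl1@rss, lo1@rss, tolerance = 1e-6)
  expect_equal(gl1@estimates, lo1@estimates, tolerance = 1e-4)
})

test_that("fit results serialize to CSV", {
  mf <- btMixed24()
  f <- withr::local_tempfile(fileext = ".csv")
  writeFitResult(mf, f)
  tab <- read.csv(f)
  expect_setequal(unique(tab$name), c("kp", "kd", "v", "kbys"))
  expect_equal(sum(tab$name == "kbys"), nWells(btCohort24()))
  expect_true(all(tab$ci_high >= tab$ci_low, na.rm = TRUE))
})
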