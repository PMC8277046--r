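test_that("cohort splitting partitions reproducibly", {
  coh <- btCohort24()
  sp <- splitCohort(coh, fraction = 0.75, seed = 5)
  expect_equal(length(sp$train), 18)
  expect_equal(length(sp$validation), 6)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), seq_len(24))
  expect_identical(splitCohort(coh, 0.75, seed = 5), sp)
  expect_false(identical(splitCohort(coh, 0.75, seed = 6)$train, sp$train))
  expect_error(splitCohort(coh, fraction = 1.2), "fraction")
  expect_error(splitCohort(coh[, 1:3]), "too small")
})

test_that("band accuracy counts covered points", {
  times <- seq(0, 4, 0.125)
  nt <- length(times)
  mkBand <- function(lo, mid, hi)
    new("PredictionBand", times = times,
        live = cbind(mean = mid, lo = lo, hi = hi),
        dead = cbind(mean = mid, lo = lo, hi = hi), nDraws = 1000L)
  pair <- list(times = times, live = rep(5, nt), dead = rep(5, nt))

  allIn <- mkBand(rep(0, nt), rep(5, nt), rep(10, nt))
  expect_equal(unname(bandAccuracy(allIn, pair)), c(1, 1))
  miss <- mkBand(rep(1, nt), rep(1, nt), rep(1, nt))
  expect_equal(unname(bandAccuracy(miss, pair)), c(0, 0))

  # 17 of 33 points covered
  lo <- rep(c(0, 9), c(17, nt - 17)); hi <- rep(c(10, 9.5), c(17, nt - 17))
  part <- mkBand(lo, (lo + hi) / 2, hi)
  expect_equal(bandAccuracy(part, pair)[["live"]], 17 / 33)

  expect_error(bandAccuracy(allIn, list(times = times[-1], live = 1, dead = 1)),
               "grid")
})

test_that("accuracy is monotone under band widening", {
  times <- seq(0, 4, 0.5)
  nt <- length(times)
  set.seed(9)
  pair <- list(times = times, live = runif(nt, 0, 10), dead = runif(nt, 0, 10))
  mid <- rep(5, nt)
  prev <- -1
  for (w in seq(0, 6, length.out = 13)) {
    band <- new("PredictionBand", times = times,
                live = cbind(mean = mid, lo = pmax(mid - w, 0), hi = mid + w),
                dead = cbind(mean = mid, lo = pmax(mid - w, 0), hi = mid + w),
                nDraws = 500L)
    acc <- mean(bandAccuracy(band, pair))
    expect_gte(acc, prev)
    prev <- acc
  }
  expect_equal(prev, 1)
})

test_that("evaluation metrics match a hand-computed toy example", {
  data <- cbind(w1 = c(10, 20, 40), w2 = c(5, 0, 10))
  model <- cbind(w1 = c(11, 18, 44), w2 = c(4, 1, 10))
  ev <- evaluateSeries(model, data)
  # spreadsheet-style reference, written out term by term
  pct <- c(100 * (11 - 10) / 10, 100 * (18 - 20) / 20, 100 * (44 - 40) / 40,
           100 * (4 - 5) / 5, 100 * (10 - 10) / 10)   # zero-data point dropped
  expect_equal(ev$mean_pct_error, mean(pct))
  expect_equal(ev$pct_error_eoe, mean(c(10, 0)))
  expect_equal(ev$mean_error, mean(c(1, -2, 4, -1, 1, 0)))
  expect_equal(ev$error_eoe, mean(c(4, 0)))
  expect_equal(ev$rss, mean(c(sum(c(1, -2, 4)^2), sum(c(-1, 1, 0)^2))) / 1e4)
  expect_equal(ev$n_excluded, 1)

  expect_equal(evaluateSeries(data, data)$mean_pct_error, 0)
  expect_equal(evaluateSeries(data, data)$rss, 0)
  ev2 <- evaluateSeries(1.1 * data, data)
  expect_equal(ev2$mean_pct_error, 10, tolerance = 1e-10)
  expect_equal(ev2$pct_error_eoe, 10, tolerance = 1e-10)
})

test_that("prediction bands collapse, reproduce and widen correctly", {
  p <- testParams(kbys = 0.3)
  est <- c(kp = 0.092, kd = 0.13, v = 2.68e-5)
  mkGlobals <- function(half) new("FitResult", estimates = est,
    ci95 = half, rss = 0, residuals = 0, nobs = 100L,
    scenario = "mixed", variant = 2L, info = list())
  law <- bystanderLaw("surface", kbys0 = 2.37e-2, alpha = 0.13,
                      ci95 = c(kbys0 = 0, alpha = 0))
  times <- seq(0, 4, 0.25)

  # all uncertainty off: the band is the deterministic trajectory
  b0 <- predictBand(mkGlobals(c(kp = 0, kd = 0, v = 0)), law, n0 = 40, g0 = 1,
                    n0Unc = 0, d0 = 0.5, times = times, nDraws = 120, seed = 3)
  expect_equal(b0@live[, "lo"], b0@live[, "hi"], tolerance = 1e-12)
  p@kbys <- evalLaw(law, 40, 1)
  tr <- simulateGrowth(40, 0.5, 1, p, times = times)
  expect_equal(unname(b0@live[, "mean"]), tr$live_pct, tolerance = 1e-6)

  half <- c(kp = 0.01, kd = 0.02, v = 3e-6)
  b1 <- predictBand(mkGlobals(half), law, 40, 1, n0Unc = 3, times = times,
                    nDraws = 200, seed = 4)
  b1b <- predictBand(mkGlobals(half), law, 40, 1, n0Unc = 3, times = times,
                     nDraws = 200, seed = 4)
  expect_identical(b1@live, b1b@live)

  # doubling the kp uncertainty widens the terminal live band
  half2 <- half; half2[["kp"]] <- 0.02
  b2 <- predictBand(mkGlobals(half2), law, 40, 1, n0Unc = 3, times = times,
                    nDraws = 200, seed = 4)
  last <- length(times)
  expect_gt(b2@live[last, "hi"] - b2@live[last, "lo"],
            b1@live[last, "hi"] - b1@live[last, "lo"])

  expect_error(predictBand(mkGlobals(half), law, 40, 1, nDraws = 50), "nDraws")
})

test_that("training uncertainty vanishes for a perfectly described cohort", {
  # frozen dynamics: constant trajectories equal constant data exactly
  times <- seq(0, 4, 0.25)
  wells <- data.frame(well_id = c("a", "b"), replicate = 1,
                      n0_pct = c(20, 40), g0_mM = 5)
  live <- cbind(rep(20, length(times)), rep(40, length(times)))
  dead <- cbind(rep(2, length(times)), rep(3, length(times)))
  coh <- growthCohort(times, live, dead, wells)
  glob <- new("FitResult", estimates = c(kp = 0, kd = 0, v = 0),
              ci95 = c(kp = 0, kd = 0, v = 0), rss = 0, residuals = 0,
              nobs = 10L, scenario = "mixed", variant = 2L, info = list())
  fit <- new("MixedFit", global = glob,
             wells = data.frame(well_id = c("a", "b"), n0_pct = c(20, 40),
                                g0_mM = 5, kbys = 0, ci95 = 0),
             rss = 0, nobs = 10L, variant = 2L)
  unc <- trainingUncertainty(fit, coh)
  expect_equal(unname(unc), c(0, 0), tolerance = 1e-10)
  expect_error(trainingUncertainty(fit, coh, ids = integer(0)), "empty")
})

test_that("short train/validate runs behave like the full procedure", {
  coh <- cachedFixture("valCohort", function()
    generateCohort(btProfile(), glucose = c(0, 0.5, 2, 5),
                   tiers = c(23.8, 51.7), replicates = 2, seed = 91))
  rv <- cachedFixture("valRun", function()
    runValidationRounds(coh, lawForm = "surface", nRounds = 2, seed = 93,
                        config = calibrationConfig(nStarts = 3, seed = 94),
                        nDraws = 300))
  expect_equal(rv$nEffective, 2)
  expect_equal(nrow(rv$rounds), 2)
  sm <- rv$summary
  get <- function(m) sm$mean[sm$metric == m]
  # live predictions are easier than dead ones (lower relative noise)
  expect_gt(get("accuracy_live"), get("accuracy_dead"))
  expect_true(get("accuracy_live") > 0.5)
  # noise in equals uncertainty out, within a factor two
  expect_gt(get("uncertainty_live"), 6.88 / 2)
  expect_lt(get("uncertainty_live"), 6.88 * 2)
  expect_true(all(c(rv$rounds$accuracy_live, rv$rounds$accuracy_dead) >= 0 &
                  c(rv$rounds$accuracy_live, rv$rounds$accuracy_dead) <= 1))
})
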