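# Shared fixtures and independent oracles. Everything is generated in code;
# heavyweight cohorts are cached per test run.

suppressPackageStartupMessages(library(SummarizedExperiment))

# default fixed constants used throughout the tests
testParams <- function(kp = 0.092, kd = 0.13, kbys = 0.2, v = 2.68e-5)
  kineticParams(kp = kp, kd = kd, kbys = kbys, v = v)

# profile variants with switched-off noise sources, for exactness checks
quietProfile <- function(base = btProfile()) {
  base@noiseLive <- 0
  base@noiseDead <- 0
  base@kbysJitter <- 0
  base
}

# independent fixed-step classic RK4 integrator over the same equations,
# written directly against the model definition (no shared code with the
# package's compiled right-hand side)
rk4Oracle <- function(n0, d0, g0, params, variant = 2, times, dt = 1e-3) {
  kp <- params@kp; kd <- params@kd; kbys <- params@kbys
  if (variant == 1) kbys <- 0
  if (variant == 3) kd <- 0
  v <- params@v * params@cellsPerPct
  th <- params@theta; gs <- params@gstar; gm <- params@gmin
  f <- function(t, y) {
    n <- max(y[1], 0); d <- max(y[2], 0); g <- max(y[3], 0)
    sd_ <- (1 - g / (g + gm)) * tanh(t)
    fd <- if (n + d > 0) d / (n + d) else 0
    starve <- kd * n * sd_
    byst <- kbys * n * fd
    c(kp * n * (1 - n / th) * (1 - sd_) - starve - byst,
      starve + byst,
      -v * n * g / (g + gs))
  }
  out <- matrix(NA_real_, length(times), 3)
  y <- c(n0, d0, g0)
  tcur <- times[1]
  out[1, ] <- y
  for (i in 2:length(times)) {
    target <- times[i]
    while (tcur < target - 1e-12) {
      h <- min(dt, target - tcur)
      k1 <- f(tcur, y)
      k2 <- f(tcur + h / 2, y + h / 2 * k1)
      k3 <- f(tcur + h / 2, y + h / 2 * k2)
      k4 <- f(tcur + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tcur <- tcur + h
    }
    out[i, ] <- y
  }
  colnames(out) <- c("live", "dead", "glucose")
  out
}

# small cached cohorts so expensive fixtures build once per test run
.fixtureCache <- new.env(parent = emptyenv())
cachedFixture <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# noisy reduced BT-474-like cohort (the acceptance-style design)
btCohort24 <- function() cachedFixture("bt24", function()
  generateCohort(btProfile(), glucose = c(0, 0.2, 0.5, 1, 2, 5),
                 tiers = c(23.8, 51.7), replicates = 2, seed = 101))

# its mixed calibration (reused by law/selection-adjacent tests)
btMixed24 <- function() cachedFixture("btmixed24", function()
  fitMixed(btCohort24(), variant = 2,
           config = calibrationConfig(nStarts = 6, seed = 102)))

# tiny noise-free cohort with constant kbys (law: flat curve), known inits
quietConstKbysCohort <- function() cachedFixture("quietconst", function() {
  prof <- quietProfile()
  prof@law <- bystanderLaw("curve", kbys0 = 0, alpha = 1, beta = 0.3)
  generateCohort(prof, glucose = c(0.2, 1, 5), tiers = 40, replicates = 1,
                 seed = 7, n0Jitter = 0)
})
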