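# Synthetic time-resolved microscopy cohorts.
#
# The generator emulates the experimental design the analysis assumes: a
# 96-well plate seeded at several confluence tiers, medium changed at t = 0
# to one of ten glucose concentrations, live and dead confluence read every
# 3 h for 4 days (33 timepoints). Observations carry multiplicative Gaussian
# noise at the profile's live/dead levels.

# evaluate under a local, restored-afterwards RNG state
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Built-in cell-line profiles for the synthetic generator
#'
#' Two contrasting parameter profiles, named after the breast-cancer lines
#' whose published kinetics they emulate:
#' \describe{
#'   \item{`btProfile()`}{BT-474-like: slower proliferation (kp = 0.092/day),
#'     high starvation death (kd = 0.13/day), v = 2.68e-5 mM/cell/day, and a
#'     confluence-dependent bystander *surface* law
#'     `kbys = kbys0 * N0 * exp(-0.13 * G0)`. Readout noise 6.88% (live) and
#'     30.83% (dead); seeding tiers 23.8/35.9/51.7%.}
#'   \item{`mdaProfile()`}{MDA-MB-231-like: faster proliferation
#'     (kp = 0.14/day), low starvation death (kd = 0.041/day),
#'     v = 4.48e-5 mM/cell/day, and a confluence-independent bystander
#'     *curve* law `kbys = 0.71 * exp(-0.98 * G0) + 0.22` /day. Readout
#'     noise 5.17% (live) and 16.78% (dead); tiers 36.9/56.2/71.9%.}
#' }
#' The surface-law amplitude is a per-cell rate on the 1e-5 scale; in the
#' generator it acts on the cell count, i.e. the per-confluence-% amplitude
#' is `2.37e-5 * cellsPerPct`.
#'
#' @param cellsPerPct cells per confluence percent (see
#'   [KineticParams-class]).
#' @return A [CellLineProfile-class].
#' @export
btProfile <- function(cellsPerPct = 1000) {
  new("CellLineProfile", name = "BT474like",
      params = kineticParams(kp = 0.092, kd = 0.13, kbys = NA_real_,
                             v = 2.68e-5, cellsPerPct = cellsPerPct),
      law = bystanderLaw("surface", kbys0 = 2.37e-5 * cellsPerPct, alpha = 0.13),
      noiseLive = 6.88, noiseDead = 30.83,
      tiers = c(low = 23.8, mid = 35.9, high = 51.7),
      kbysJitter = 0.1, d0 = 0.5)
}

#' @rdname btProfile
#' @export
mdaProfile <- function(cellsPerPct = 1000) {
  new("CellLineProfile", name = "MDA231like",
      params = kineticParams(kp = 0.14, kd = 0.041, kbys = NA_real_,
                             v = 4.48e-5, cellsPerPct = cellsPerPct),
      law = bystanderLaw("curve", kbys0 = 0.71, alpha = 0.98, beta = 0.22),
      noiseLive = 5.17, noiseDead = 16.78,
      tiers = c(low = 36.9, mid = 56.2, high = 71.9),
      kbysJitter = 0.1, d0 = 0.5)
}

#' The experiment's glucose design grid
#'
#' @return The ten initial glucose concentrations (mM) of the emulated
#'   design.
#' @export
designGlucoseLevels <- function() c(0, 0.1, 0.2, 0.5, 0.8, 1, 2, 5, 8, 10)

#' Generate a noisy synthetic cohort
#'
#' For every well of the `glucose x tiers x replicates` design the seeding
#' confluence is drawn around its tier anchor (Gaussian, sd `n0Jitter`), the
#' initial dead confluence around the profile's `d0` (lognormal, sd 0.1),
#' the well's bystander rate is the profile law evaluated at `(N0, G0)` with
#' lognormal jitter (`kbysJitter`), the complete model (variant 2) is
#' simulated, and i.i.d. multiplicative Gaussian noise at the profile's
#' live/dead levels is added (truncated at 0). Fully reproducible for a
#' given seed. The generating per-well values (`true_kbys`, `d0_pct`) are
#' kept in `colData` so recovery can be scored.
#'
#' @param profile a [CellLineProfile-class].
#' @param glucose initial glucose levels, mM.
#' @param tiers seeding-confluence anchors, %; defaults to the profile's.
#' @param replicates wells per (glucose, tier) condition.
#' @param times sampling grid, days (every 3 h for 4 days by default).
#' @param seed integer seed.
#' @param n0Jitter sd of the seeding-confluence draw, %.
#' @return A [GrowthCohort-class].
#' @examples
#' coh <- generateCohort(btProfile(), glucose = c(0.2, 5), replicates = 1,
#'                       seed = 1)
#' coh
#' @export
generateCohort <- function(profile, glucose = designGlucoseLevels(),
                           tiers = profile@tiers, replicates = 4,
                           times = seq(0, 4, by = 0.125), seed = 1,
                           n0Jitter = 1.0) {
  stopifnot(is(profile, "CellLineProfile"))
  if (length(glucose) == 0 || length(tiers) == 0 || replicates < 1)
    stop("empty design: need >= 1 glucose level, tier and replicate")
  design <- expand.grid(replicate = seq_len(replicates), tier = as.numeric(tiers),
                        g0 = glucose, KEEP.OUT.ATTRS = FALSE)
  m <- nrow(design)
  withSeed(seed, {
    n0 <- pmax(design$tier + stats::rnorm(m, 0, n0Jitter), 1)
    d0 <- profile@d0 * exp(stats::rnorm(m, 0, 0.1))
    kbys <- evalLaw(profile@law, n0 = n0, g0 = design$g0) *
      exp(stats::rnorm(m, 0, profile@kbysJitter))
    live <- matrix(0, length(times), m)
    dead <- matrix(0, length(times), m)
    for (j in seq_len(m)) {
      p <- profile@params
      p@kbys <- kbys[j]
      tr <- simulateGrowth(n0[j], d0[j], design$g0[j], p, variant = 2,
                           times = times)
      live[, j] <- tr$live_pct
      dead[, j] <- tr$dead_pct
    }
    nlive <- length(live)
    live <- pmax(live * (1 + stats::rnorm(nlive, 0, profile@noiseLive / 100)), 0)
    dead <- pmax(dead * (1 + stats::rnorm(length(dead), 0, profile@noiseDead / 100)), 0)
  })
  wells <- data.frame(
    well_id = sprintf("%s_w%03d", profile@name, seq_len(m)),
    replicate = design$replicate,
    n0_pct = n0, g0_mM = design$g0, tier_pct = design$tier,
    d0_pct = d0, true_kbys = kbys)
  growthCohort(times, live, dead, wells,
               metadata = list(profile = profile@name, seed = seed,
                               design = c(glucose = length(glucose),
                                          tiers = length(tiers),
                                          replicates = replicates),
                               noise = c(live = profile@noiseLive,
                                         dead = profile@noiseDead)))
}

#' Draw noisy bystander-rate samples from a law
#'
#' Fixture generator for law-fitting: evaluates a [BystanderLaw-class] at a
#' set of initial conditions and adds Gaussian noise (absolute sd `noiseSd`
#' plus relative sd `relNoise * value`), truncated at 0, with a synthetic
#' 95% CI half-width of 1.96 times the per-sample noise sd.
#'
#' @param law a [BystanderLaw-class].
#' @param conditions data.frame with columns `n0` (ignored for the curve
#'   form) and `g0`.
#' @param noiseSd absolute noise sd, day^-1.
#' @param relNoise relative noise sd (fraction of the true value).
#' @param seed integer seed.
#' @return data.frame with columns `n0`, `g0`, `true_kbys`, `kbys`, `ci`.
#' @export
generateLawSamples <- function(law, conditions, noiseSd = 0, relNoise = 0,
                               seed = 1) {
  stopifnot(is(law, "BystanderLaw"))
  if (is.null(conditions$g0) || nrow(conditions) == 0)
    stop("conditions must be a non-empty data.frame with a g0 column")
  if (noiseSd < 0 || relNoise < 0) stop("noise levels must be >= 0")
  n0 <- if (is.null(conditions$n0)) rep(NA_real_, nrow(conditions)) else conditions$n0
  truth <- evalLaw(law, n0 = n0, g0 = conditions$g0)
  sd_ <- noiseSd + relNoise * abs(truth)
  obs <- withSeed(seed, pmax(truth + stats::rnorm(length(truth), 0, sd_), 0))
  data.frame(n0 = n0, g0 = conditions$g0, true_kbys = truth, kbys = obs,
             ci = 1.96 * sd_)
}
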