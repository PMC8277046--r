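# Repeated train/validate machinery: random 75/25 splits, mixed calibration
# on the training wells, bystander-law transfer, Monte-Carlo prediction
# bands on the validation wells, and the error/accuracy scoring metrics.

#' Random train/validation split of a cohort
#'
#' Uniform partition of the wells without replacement.
#'
#' @param cohort a [GrowthCohort-class].
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer well indices `train` and `validation`, plus
#'   `seed` and `fraction`.
#' @export
splitCohort <- function(cohort, fraction = 0.75, seed = 1) {
  m <- nWells(cohort)
  if (m < 4) stop("cohort too small to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ntrain <- round(fraction * m)
  train <- withSeed(seed, sort(sample.int(m, ntrain)))
  list(train = train, validation = setdiff(seq_len(m), train),
       seed = seed, fraction = fraction)
}

# model trajectories for a set of wells under a MixedFit (shared rates +
# per-well kbys), started from the first-three-timepoint initial estimates
fittedTrajectories <- function(fit, cohort, ids = seq_len(nWells(cohort)),
                               constants = defaultConstants(),
                               ctl = list(odeMethod = "lsoda", rtol = 1e-8,
                                          atol = 1e-10)) {
  stopifnot(is(fit, "MixedFit"))
  est <- fit@global@estimates
  times <- cohortTimes(cohort)
  # calibration anchors each well at the second timepoint (the center of
  # the initial-state averaging window); score the same points
  keep <- 2:length(times)
  live <- dead <- matrix(NA_real_, length(keep), length(ids))
  for (k in seq_along(ids)) {
    pair <- getPair(cohort, ids[k])
    init <- estimateInitialState(pair)
    row <- match(pair$well_id, fit@wells$well_id)
    if (is.na(row)) stop("well ", pair$well_id, " not covered by the fit")
    parmvec <- c(est[["kp"]], if ("kd" %in% names(est)) est[["kd"]] else 0,
                 fit@wells$kbys[row], est[["v"]],
                 constants@theta, constants@gstar, constants@gmin,
                 constants@cellsPerPct)
    sim <- .simRaw(init$n0, init$d0, pair$g0, parmvec, times[keep], ctl)
    live[, k] <- sim[, 1]; dead[, k] <- sim[, 2]
  }
  list(live = live, dead = dead, ids = ids, rows = keep)
}

#' Training-set measurement uncertainty
#'
#' Mean absolute deviation between the calibrated model curves and the
#' training data, expressed as a percent of the mean signal, separately for
#' the live and dead series. Used as the initial-confluence uncertainty when
#' forming predictions.
#'
#' @param fit a [MixedFit-class] calibrated on the training wells.
#' @param cohort the cohort the fit was trained on.
#' @param ids training well indices (default: all wells of `cohort`).
#' @param constants fixed model constants.
#' @return named numeric: `live`, `dead` (percent of mean signal).
#' @export
trainingUncertainty <- function(fit, cohort, ids = seq_len(nWells(cohort)),
                                constants = defaultConstants()) {
  if (!length(ids)) stop("empty training set")
  tr <- fittedTrajectories(fit, cohort, ids, constants)
  obsL <- assay(cohort, "live")[tr$rows, ids, drop = FALSE]
  obsD <- assay(cohort, "dead")[tr$rows, ids, drop = FALSE]
  c(live = 100 * mean(abs(tr$live - obsL)) / mean(obsL),
    dead = 100 * mean(abs(tr$dead - obsD)) / mean(obsD))
}

# draw from N(mean, sd) truncated at zero (mass below zero moved to zero;
# CI half-widths are converted to sd via the normal 97.5% quantile)
.truncDraw <- function(n, mean, half) {
  sd <- ifelse(is.na(half), 0, half / stats::qnorm(0.975))
  pmax(stats::rnorm(n, mean, sd), 0)
}

#' Monte-Carlo prediction band for one well
#'
#' Propagates parameter and initial-condition uncertainty through the
#' forward model: the shared rates are drawn from independent normals
#' centred at their estimates with sd set by their 95% CI half-widths
#' (truncated at 0), the initial live confluence from its training-derived
#' uncertainty, and the well's `kbys` by evaluating the bystander law with
#' its parameters drawn from their CIs. Each draw is simulated and the band
#' is the pointwise mean and 2.5/97.5 percentiles.
#'
#' @param globals a [FitResult-class] carrying the shared `kp`, `kd`, `v`
#'   estimates and CIs (e.g. the `global` slot of a [MixedFit-class]).
#' @param law a [BystanderLaw-class] fitted on the training set.
#' @param n0 initial live confluence, % (typically the first-three-point
#'   estimate).
#' @param g0 initial glucose, mM.
#' @param n0Unc uncertainty of `n0`, percent of signal (from
#'   [trainingUncertainty()]); the draw sd is `n0 * n0Unc / 100`.
#' @param d0 initial dead confluence, %.
#' @param times output grid, days.
#' @param nDraws Monte-Carlo draw count (>= 100).
#' @param seed integer seed.
#' @param constants fixed model constants.
#' @param variant model variant for the forward runs.
#' @return A [PredictionBand-class].
#' @export
predictBand <- function(globals, law, n0, g0, n0Unc = 0, d0 = 0.5,
                        times = seq(0, 4, by = 0.125), nDraws = 1000,
                        seed = 1, constants = defaultConstants(),
                        variant = 2) {
  stopifnot(is(globals, "FitResult"), is(law, "BystanderLaw"))
  if (nDraws < 100) stop("nDraws < 100: band would be unstable")
  est <- globals@estimates; half <- globals@ci95
  ctl <- list(odeMethod = "lsoda", rtol = 1e-8, atol = 1e-10)
  nt <- length(times)
  live <- dead <- matrix(NA_real_, nt, nDraws)
  withSeed(seed, {
    kp <- .truncDraw(nDraws, est[["kp"]], half[["kp"]])
    kd <- if ("kd" %in% names(est)) .truncDraw(nDraws, est[["kd"]], half[["kd"]]) else rep(0, nDraws)
    v <- .truncDraw(nDraws, est[["v"]], half[["v"]])
    n0d <- pmax(stats::rnorm(nDraws, n0, n0 * n0Unc / 100), 0)
    k0d <- .truncDraw(nDraws, law@kbys0, law@ci95[["kbys0"]])
    ald <- .truncDraw(nDraws, law@alpha, law@ci95[["alpha"]])
    bed <- if (law@form == "curve") .truncDraw(nDraws, law@beta, law@ci95[["beta"]]) else rep(NA_real_, nDraws)
    for (i in seq_len(nDraws)) {
      lawi <- law
      lawi@kbys0 <- k0d[i]; lawi@alpha <- ald[i]
      if (law@form == "curve") lawi@beta <- bed[i]
      kbys <- evalLaw(lawi, n0 = n0d[i], g0 = g0)
      if (variant == 1) kbys <- 0
      kdi <- if (variant == 3) 0 else kd[i]
      parmvec <- c(kp[i], kdi, kbys, v[i], constants@theta, constants@gstar,
                   constants@gmin, constants@cellsPerPct)
      sim <- .simRaw(n0d[i], d0, g0, parmvec, times, ctl)
      live[, i] <- sim[, 1]; dead[, i] <- sim[, 2]
    }
  })
  bandOf <- function(m) {
    q <- t(apply(m, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
    out <- cbind(mean = rowMeans(m), lo = pmin(q[, 1], rowMeans(m)),
                 hi = pmax(q[, 2], rowMeans(m)))
    out
  }
  new("PredictionBand", times = times, live = bandOf(live),
      dead = bandOf(dead), nDraws = as.integer(nDraws))
}

#' Fraction of measured points inside a prediction band
#'
#' @param band a [PredictionBand-class].
#' @param pair a time-course pair from [getPair()] on the same grid.
#' @return named numeric: `live`, `dead`, each the covered fraction in
#'   \[0, 1\].
#' @export
bandAccuracy <- function(band, pair) {
  if (length(band@times) != length(pair$times) ||
      any(abs(band@times - pair$times) > 1e-9))
    stop("band grid does not match the pair's timepoints")
  inside <- function(m, x) mean(x >= m[, "lo"] & x <= m[, "hi"])
  c(live = inside(band@live, pair$live), dead = inside(band@dead, pair$dead))
}

#' Error metrics between model and measured series
#'
#' Computes, for aligned model/data matrices (timepoints x wells, confluence
#' %): RSS on fractional confluence averaged per well; signed mean percent
#' error over all points; percent error at the end of experiment (EoE, last
#' timepoint); and their unnormalized analogs in confluence %. Points whose
#' data value is exactly zero are excluded from the percent-error means and
#' counted.
#'
#' @param model,data numeric matrices (or vectors) of equal shape.
#' @return list: `rss`, `mean_pct_error`, `pct_error_eoe`, `mean_error`,
#'   `error_eoe`, `n_excluded`.
#' @export
evaluateSeries <- function(model, data) {
  model <- as.matrix(model); data <- as.matrix(data)
  if (!all(dim(model) == dim(data))) stop("model and data must be aligned")
  err <- model - data
  last <- nrow(data)
  nz <- data != 0
  pct <- 100 * err / data
  list(rss = mean(colSums((err / 100)^2)),
       mean_pct_error = mean(pct[nz]),
       pct_error_eoe = mean(pct[last, nz[last, ], drop = TRUE]),
       mean_error = mean(err),
       error_eoe = mean(err[last, ]),
       n_excluded = sum(!nz))
}

#' Repeated train/validate rounds
#'
#' Each round: split the cohort (75/25 by default), run the mixed
#' calibration on the training wells, fit the bystander law to the training
#' per-well `kbys` estimates, measure the training uncertainty, then predict
#' every validation well from its initial conditions alone and score
#' accuracy and the error metrics. Rounds whose calibration fails are
#' skipped and logged.
#'
#' @param cohort a [GrowthCohort-class].
#' @param lawForm `"surface"` or `"curve"` (the cell line's law family).
#' @param nRounds number of rounds (>= 2).
#' @param fraction training fraction.
#' @param seed integer seed; round r uses `seed + r`.
#' @param config a [calibrationConfig()].
#' @param constants fixed model constants.
#' @param nDraws Monte-Carlo draws per prediction band.
#' @return list with `rounds` (per-round data.frame of metrics), `summary`
#'   (across-round mean and normal-approximation 95% CI per metric and
#'   series), and `nEffective` (rounds that completed).
#' @export
runValidationRounds <- function(cohort, lawForm = c("surface", "curve"),
                                nRounds = 50, fraction = 0.75, seed = 1,
                                config = calibrationConfig(),
                                constants = defaultConstants(),
                                nDraws = 1000) {
  lawForm <- match.arg(lawForm)
  if (nRounds < 2) stop("need >= 2 rounds")
  rows <- list()
  for (r in seq_len(nRounds)) {
    res <- tryCatch({
      sp <- splitCohort(cohort, fraction, seed = seed + r)
      sub <- cohort[, sp$train]
      fit <- fitMixed(sub, variant = 2,
                      config = calibrationConfig(
                        nStarts = config$nStarts, seed = config$seed + r,
                        ftol = config$ftol, ptol = config$ptol,
                        maxiter = config$maxiter, odeMethod = config$odeMethod,
                        rtol = config$rtol, atol = config$atol),
                      constants = constants)
      samples <- data.frame(n0 = fit@wells$n0_pct, g0 = fit@wells$g0_mM,
                            kbys = fit@wells$kbys, ci = fit@wells$ci95)
      law <- if (lawForm == "surface") fitSurfaceLaw(samples) else fitCurveLaw(samples)
      unc <- trainingUncertainty(fit, cohort, sp$train, constants)
      accL <- accD <- numeric(0)
      predL <- predD <- obsL <- obsD <- NULL
      for (j in sp$validation) {
        pair <- getPair(cohort, j)
        init <- estimateInitialState(pair)
        band <- predictBand(fit@global, law, n0 = init$n0, g0 = pair$g0,
                            n0Unc = unc[["live"]], d0 = init$d0,
                            times = pair$times, nDraws = nDraws,
                            seed = seed + 1000L * r + j,
                            constants = constants)
        a <- bandAccuracy(band, pair)
        accL <- c(accL, a[["live"]]); accD <- c(accD, a[["dead"]])
        predL <- cbind(predL, band@live[, "mean"])
        predD <- cbind(predD, band@dead[, "mean"])
        obsL <- cbind(obsL, pair$live); obsD <- cbind(obsD, pair$dead)
      }
      evL <- evaluateSeries(predL, obsL); evD <- evaluateSeries(predD, obsD)
      data.frame(round = r,
                 accuracy_live = mean(accL), accuracy_dead = mean(accD),
                 rss_live = evL$rss, rss_dead = evD$rss,
                 mean_pct_error_live = evL$mean_pct_error,
                 mean_pct_error_dead = evD$mean_pct_error,
                 pct_error_eoe_live = evL$pct_error_eoe,
                 pct_error_eoe_dead = evD$pct_error_eoe,
                 mean_error_live = evL$mean_error,
                 mean_error_dead = evD$mean_error,
                 error_eoe_live = evL$error_eoe,
                 error_eoe_dead = evD$error_eoe,
                 uncertainty_live = unc[["live"]],
                 uncertainty_dead = unc[["dead"]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("round ", r, " skipped: ", conditionMessage(res))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("every round failed")
  rounds <- do.call(rbind, rows)
  mets <- setdiff(names(rounds), "round")
  summary <- do.call(rbind, lapply(mets, function(mname) {
    x <- rounds[[mname]]
    data.frame(metric = mname, mean = mean(x),
               ci95 = 1.96 * stats::sd(x) / sqrt(length(x)))
  }))
  list(rounds = rounds, summary = summary, nEffective = nrow(rounds))
}
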