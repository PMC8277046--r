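# Multistart nonlinear least-squares calibration.
#
# Three parameter-sharing scenarios:
#   local  - every well gets its own free kinetic parameters;
#   global - one shared parameter vector for the whole cohort;
#   mixed  - kp, kd, v shared, kbys free per well.
# All scenarios minimize the RSS of the concatenated (unweighted) live and
# dead confluence residuals. Optimization runs in log10 parameter space
# (positivity and scale disparity between day^-1 rates and the 1e-5-scale
# consumption rate are handled at once) with bounded Levenberg-Marquardt;
# each solve is restarted from several log-uniform initial guesses and the
# lowest-RSS solution wins. 95% CIs are linearized from the natural-scale
# Jacobian at the optimum.

#' Calibration settings
#'
#' @param nStarts multistart count (log-uniform initial guesses).
#' @param seed integer seed for the multistart draws.
#' @param lower,upper named optimizer bounds for `kp`, `kd`, `kbys`
#'   (day^-1) and `v` (mM cell^-1 day^-1).
#' @param guessLower,guessUpper named ranges of the log-uniform initial
#'   guesses (rates in \[1e-3, 2\] day^-1, `v` in \[1e-7, 1e-3\]).
#' @param ftol,ptol,maxiter Levenberg-Marquardt convergence controls.
#' @param odeMethod,rtol,atol forward-simulation settings used inside the
#'   objective.
#' @return list of class `calibrationConfig`.
#' @export
calibrationConfig <- function(nStarts = 10, seed = 1,
                              lower = c(kp = 1e-7, kd = 1e-7, kbys = 1e-7, v = 1e-8),
                              upper = c(kp = 5, kd = 5, kbys = 5, v = 1e-3),
                              guessLower = c(kp = 1e-3, kd = 1e-3, kbys = 1e-3, v = 1e-7),
                              guessUpper = c(kp = 2, kd = 2, kbys = 2, v = 1e-3),
                              ftol = 1e-10, ptol = 1e-8, maxiter = 200,
                              odeMethod = "lsoda", rtol = 1e-8, atol = 1e-10) {
  stopifnot(nStarts >= 1, all(lower >= 0), all(upper > lower))
  structure(list(nStarts = as.integer(nStarts), seed = as.integer(seed),
                 lower = lower, upper = upper, guessLower = guessLower,
                 guessUpper = guessUpper, ftol = ftol, ptol = ptol,
                 maxiter = as.integer(maxiter), odeMethod = odeMethod,
                 rtol = rtol, atol = atol),
            class = "calibrationConfig")
}

# free kinetic parameters per model variant
freeParamNames <- function(variant) {
  switch(checkVariant(variant),
         c("kp", "kd", "v"),            # 1: no bystander term
         c("kp", "kd", "kbys", "v"),    # 2: complete model
         c("kp", "kbys", "v"))          # 3: no starvation-death term
}

#' Estimate a well's initial state from its time course
#'
#' The initial live and dead confluence are taken as the mean of the first
#' three timepoints, damping single-timepoint measurement error.
#'
#' @param pair a time-course pair as returned by [getPair()] (any list with
#'   `live` and `dead` series of >= 3 points).
#' @return list with `n0`, `d0` (means, %) and `n0_se`, `d0_se` (standard
#'   errors of those means).
#' @export
estimateInitialState <- function(pair) {
  if (length(pair$live) < 3 || length(pair$dead) < 3)
    stop("need >= 3 timepoints to estimate the initial state")
  l <- pair$live[1:3]; d <- pair$dead[1:3]
  list(n0 = mean(l), d0 = mean(d),
       n0_se = stats::sd(l) / sqrt(3), d0_se = stats::sd(d) / sqrt(3))
}

# fast raw simulation used inside objectives: returns T x 2 matrix (live,
# dead); parmvec = c(kp, kd, kbys, v, theta, gstar, gmin, cellsPerPct)
.simRaw <- function(n0, d0, g0, parmvec, times, ctl) {
  out <- deSolve::ode(y = c(n0, d0, g0), times = times,
                      func = "glucodyn_derivs", parms = parmvec,
                      dllname = "glucodyn", initfunc = "glucodyn_initmod",
                      method = ctl$odeMethod, rtol = ctl$rtol, atol = ctl$atol)
  if (nrow(out) < length(times))
    stop(sprintf("integration failed at t = %.4g days", out[nrow(out), 1]))
  m <- out[, 2:3, drop = FALSE]
  m[m < 0] <- 0
  m
}

# assemble per-well prepared data (initial-state estimates, observations);
# inits optionally overrides the first-three-timepoint heuristic with known
# initial states at t = 0 (data.frame with n0, d0 rows aligned to the wells).
# The three-point average estimates the state at the center of the averaging
# window, so without known inits the trajectory is anchored at the second
# timepoint and residuals are scored from there on; the t = 0 observation
# has already been spent on the initial-state estimate.
.prepWells <- function(cohort, inits = NULL) {
  lapply(seq_len(nWells(cohort)), function(i) {
    pair <- getPair(cohort, i)
    if (is.null(inits)) {
      init <- estimateInitialState(pair)
      keep <- 2:length(pair$times)
      list(well_id = pair$well_id, times = pair$times[keep],
           live = pair$live[keep], dead = pair$dead[keep],
           n0 = init$n0, d0 = init$d0, g0 = pair$g0, n0_obs = pair$n0)
    } else {
      list(well_id = pair$well_id, times = pair$times, live = pair$live,
           dead = pair$dead, n0 = inits$n0[i], d0 = inits$d0[i],
           g0 = pair$g0, n0_obs = pair$n0)
    }
  })
}

# residuals of one well under a named natural-scale parameter set
.residWell <- function(w, p, consts, ctl) {
  parmvec <- c(p[["kp"]], p[["kd"]], p[["kbys"]], p[["v"]],
               consts@theta, consts@gstar, consts@gmin, consts@cellsPerPct)
  sim <- .simRaw(w$n0, w$d0, w$g0, parmvec, w$times, ctl)
  c(sim[, 1] - w$live, sim[, 2] - w$dead)
}

# expand the optimizer vector (log10) into per-well natural parameter sets
.expandTheta <- function(lt, sharedNames, perWell, m) {
  nat <- 10^lt
  full <- c(kp = 0, kd = 0, kbys = 0, v = 0)
  full[sharedNames] <- nat[seq_along(sharedNames)]
  if (perWell) {
    kb <- nat[length(sharedNames) + seq_len(m)]
  } else kb <- rep(full[["kbys"]], m)
  list(shared = full, kbys = kb)
}

# pooled residual vector for the whole well set
.costLS <- function(lt, wells, sharedNames, perWell, consts, ctl) {
  th <- .expandTheta(lt, sharedNames, perWell, length(wells))
  unlist(lapply(seq_along(wells), function(j) {
    p <- th$shared
    p[["kbys"]] <- th$kbys[j]
    .residWell(wells[[j]], p, consts, ctl)
  }), use.names = FALSE)
}

# structured forward-difference Jacobian: shared parameters perturb every
# well; each per-well kbys perturbs only its own well's residual block
.jacLS <- function(lt, wells, sharedNames, perWell, consts, ctl, h = 1e-5) {
  m <- length(wells)
  nper <- vapply(wells, function(w) 2L * length(w$times), integer(1))
  offs <- c(0L, cumsum(nper))
  r0 <- .costLS(lt, wells, sharedNames, perWell, consts, ctl)
  np <- length(lt)
  J <- matrix(0, length(r0), np)
  for (k in seq_along(sharedNames)) {
    ltk <- lt; ltk[k] <- ltk[k] + h
    J[, k] <- (.costLS(ltk, wells, sharedNames, perWell, consts, ctl) - r0) / h
  }
  if (perWell) {
    th <- .expandTheta(lt, sharedNames, perWell, m)
    for (j in seq_len(m)) {
      k <- length(sharedNames) + j
      p <- th$shared
      p[["kbys"]] <- 10^(lt[k] + h)
      rj <- .residWell(wells[[j]], p, consts, ctl)
      rows <- (offs[j] + 1L):offs[j + 1L]
      J[rows, k] <- (rj - r0[rows]) / h
    }
  }
  J
}

# natural-scale Jacobian at the optimum (for linearized CIs); same block
# structure, relative central differences
.jacNatural <- function(par, wells, sharedNames, perWell, consts, ctl,
                        relStep = 1e-5) {
  logp <- log10(pmax(par, 1e-300))
  h <- relStep / log(10)   # log10 step equivalent to a relative step
  m <- length(wells)
  J <- .jacLS(logp, wells, sharedNames, perWell, consts, ctl, h = h)
  # d r / d p = (d r / d log10 p) / (p ln 10)
  sweep(J, 2, par * log(10), "/")
}

# multistart bounded LM over a well set; the workhorse behind fitPair,
# fitGlobal and fitMixed
.fitLS <- function(wells, variant, config, scenario, perWell, computeCI = TRUE) {
  consts <- config$constants
  sharedNames <- freeParamNames(variant)
  if (perWell) sharedNames <- setdiff(sharedNames, "kbys")
  if (perWell && !"kbys" %in% freeParamNames(variant))
    stop("per-well kbys requested for a variant without a bystander term")
  m <- length(wells)
  ctl <- config[c("odeMethod", "rtol", "atol")]
  nsh <- length(sharedNames)
  np <- nsh + if (perWell) m else 0L
  lower <- log10(c(config$lower[sharedNames], rep(config$lower[["kbys"]], if (perWell) m else 0)))
  upper <- log10(c(config$upper[sharedNames], rep(config$upper[["kbys"]], if (perWell) m else 0)))
  gnames <- c(sharedNames, if (perWell) "kbys")
  starts <- withSeed(config$seed, {
    g <- matrix(stats::runif(config$nStarts * length(gnames),
                             log10(config$guessLower[gnames]),
                             log10(config$guessUpper[gnames])),
                nrow = config$nStarts, byrow = TRUE)
    g
  })
  ctrl <- minpack.lm::nls.lm.control(ftol = config$ftol, ptol = config$ptol,
                                     maxiter = config$maxiter)
  best <- NULL
  startRss <- rep(NA_real_, config$nStarts)
  for (s in seq_len(config$nStarts)) {
    st <- starts[s, ]
    par0 <- c(st[seq_len(nsh)], rep(st[length(st)], if (perWell) m else 0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(par0, lower), upper),
                         fn = .costLS, jac = .jacLS,
                         wells = wells, sharedNames = sharedNames,
                         perWell = perWell, consts = consts, ctl = ctl,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    startRss[s] <- fit$deviance
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("calibration failed: no multistart run converged (", m, " wells, variant ",
         variant, ")")
  par <- 10^best$par
  names(par) <- c(sharedNames, if (perWell) paste0("kbys.", seq_len(m)))
  resid <- .costLS(best$par, wells, sharedNames, perWell, consts, ctl)
  ci <- rep(NA_real_, length(par))
  if (computeCI) {
    Jn <- .jacNatural(par, wells, sharedNames, perWell, consts, ctl)
    ci <- tryCatch(ciLinearized(resid, Jn), error = function(e) {
      warning("CI computation failed: ", conditionMessage(e))
      rep(NA_real_, length(par))
    })
  }
  names(ci) <- names(par)
  list(par = par, sharedNames = sharedNames, perWell = perWell, ci = ci,
       rss = sum(resid^2), residuals = resid, nobs = length(resid),
       info = list(startRss = startRss, niter = best$niter,
                   message = best$message, nStarts = config$nStarts,
                   seed = config$seed))
}

# attach the fixed model constants to a config (calibration never fits
# theta, G*, Gmin or the cell conversion; they come from a template)
.withConstants <- function(config, constants) {
  if (is.null(config$constants)) config$constants <- constants
  config
}

defaultConstants <- function() kineticParams(kp = 0, kd = 0, kbys = 0, v = 0)

#' Calibrate one well's time-course pair (local scenario)
#'
#' Fits the variant's free kinetic parameters to a single live/dead pair by
#' multistart bounded least squares; `theta`, `G*`, `Gmin` and the cell
#' conversion stay fixed at the values in `constants`.
#'
#' @param pair a pair from [getPair()].
#' @param variant model variant (1, 2 or 3).
#' @param config a [calibrationConfig()].
#' @param constants [KineticParams-class] supplying the fixed constants.
#' @param init optional list with known `n0`, `d0`; by default the
#'   first-three-timepoint estimate of [estimateInitialState()] is used.
#' @param computeCI compute linearized CIs (skip for speed when only the
#'   RSS is needed, e.g. inside model selection).
#' @return A [FitResult-class].
#' @export
fitPair <- function(pair, variant = 2, config = calibrationConfig(),
                    constants = defaultConstants(), init = NULL,
                    computeCI = TRUE) {
  if (is.null(init)) {
    init <- estimateInitialState(pair)
    keep <- 2:length(pair$times)
    w <- list(list(well_id = pair$well_id, times = pair$times[keep],
                   live = pair$live[keep], dead = pair$dead[keep],
                   n0 = init$n0, d0 = init$d0, g0 = pair$g0))
  } else {
    w <- list(list(well_id = pair$well_id, times = pair$times,
                   live = pair$live, dead = pair$dead,
                   n0 = init$n0, d0 = init$d0, g0 = pair$g0))
  }
  config <- .withConstants(config, constants)
  r <- .fitLS(w, variant, config, "local", perWell = FALSE,
              computeCI = computeCI)
  new("FitResult", estimates = r$par, ci95 = r$ci, rss = r$rss,
      residuals = r$residuals, nobs = as.integer(r$nobs),
      scenario = "local", variant = as.integer(checkVariant(variant)),
      info = r$info)
}

#' Calibrate shared parameters for a whole cohort (global scenario)
#'
#' One parameter vector minimizes the pooled RSS over every well's live and
#' dead residuals.
#'
#' @param cohort a [GrowthCohort-class].
#' @param inits optional data.frame of known initial states (`n0`, `d0`),
#'   one row per well, overriding the first-three-timepoint estimates.
#' @inheritParams fitPair
#' @return A [FitResult-class].
#' @export
fitGlobal <- function(cohort, variant = 2, config = calibrationConfig(),
                      constants = defaultConstants(), inits = NULL) {
  if (nWells(cohort) == 0) stop("empty cohort")
  config <- .withConstants(config, constants)
  wells <- .prepWells(cohort, inits)
  r <- .fitLS(wells, variant, config, "global", perWell = FALSE)
  new("FitResult", estimates = r$par, ci95 = r$ci, rss = r$rss,
      residuals = r$residuals, nobs = as.integer(r$nobs),
      scenario = "global", variant = as.integer(checkVariant(variant)),
      info = r$info)
}

#' Mixed calibration: shared rates plus per-well bystander rate
#'
#' Jointly optimizes the shared parameters (`kp`, `kd`, `v` for the complete
#' model) and one `kbys` per well, in a single bounded least-squares problem
#' whose Jacobian exploits the block structure (each `kbys` touches only its
#' own well's residuals). Per-well `kbys` CIs come from the joint Jacobian.
#'
#' @inheritParams fitGlobal
#' @return A [MixedFit-class].
#' @export
fitMixed <- function(cohort, variant = 2, config = calibrationConfig(),
                     constants = defaultConstants(), inits = NULL) {
  if (nWells(cohort) == 0) stop("empty cohort")
  config <- .withConstants(config, constants)
  wells <- .prepWells(cohort, inits)
  r <- .fitLS(wells, variant, config, "mixed", perWell = TRUE)
  nsh <- length(r$sharedNames)
  shared <- r$par[seq_len(nsh)]
  info <- wellInfo(cohort)
  wellTab <- data.frame(well_id = info$well_id, n0_pct = info$n0_pct,
                        g0_mM = info$g0_mM,
                        kbys = unname(r$par[nsh + seq_len(nWells(cohort))]),
                        ci95 = unname(r$ci[nsh + seq_len(nWells(cohort))]))
  globalFit <- new("FitResult", estimates = shared,
                   ci95 = r$ci[seq_len(nsh)], rss = r$rss,
                   residuals = r$residuals, nobs = as.integer(r$nobs),
                   scenario = "mixed", variant = as.integer(checkVariant(variant)),
                   info = r$info)
  new("MixedFit", global = globalFit, wells = wellTab, rss = r$rss,
      nobs = as.integer(r$nobs), variant = as.integer(checkVariant(variant)))
}

#' Linearized (Gauss-Newton) confidence intervals
#'
#' Standard nonlinear-regression intervals from the residual vector and the
#' Jacobian at the optimum: half-width
#' `t(1 - a/2, n - p) * sqrt(s^2 * [(J'J)^-1]_kk)` with
#' `s^2 = RSS / (n - p)`.
#'
#' @param residuals residual vector at the optimum (length n).
#' @param jacobian n x p Jacobian of the residuals wrt the parameters.
#' @param level confidence level.
#' @return Named numeric of CI half-widths (per column of `jacobian`); the
#'   standard errors are attached as attribute `"se"`.
#' @export
ciLinearized <- function(residuals, jacobian, level = 0.95) {
  jacobian <- as.matrix(jacobian)
  n <- length(residuals); p <- ncol(jacobian)
  if (n <= p) stop("need more observations than parameters")
  qrJ <- qr(jacobian)
  if (qrJ$rank < p) {
    bad <- setdiff(seq_len(p), qrJ$pivot[seq_len(qrJ$rank)])
    nm <- colnames(jacobian)
    lab <- if (is.null(nm)) paste0("column ", bad) else nm[bad]
    stop("non-identifiable: Jacobian rank ", qrJ$rank, " < ", p,
         "; degenerate direction(s): ", paste(lab, collapse = ", "))
  }
  s2 <- sum(residuals^2) / (n - p)
  R <- qr.R(qrJ)
  # unscramble the QR pivoting
  Rinv <- backsolve(R, diag(p))
  cov <- tcrossprod(Rinv) * s2
  piv <- qrJ$pivot
  se <- numeric(p)
  se[piv] <- sqrt(diag(cov))
  half <- stats::qt(1 - (1 - level) / 2, df = n - p) * se
  names(half) <- colnames(jacobian)
  attr(half, "se") <- se
  half
}

#' Serialize fit results to CSV
#'
#' One row per parameter: name, estimate, CI bounds, scenario, variant and
#' well id (`"global"` for shared parameters).
#'
#' @param fit a [FitResult-class] or [MixedFit-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeFitResult <- function(fit, path) {
  rowsOf <- function(f, well) {
    data.frame(name = names(f@estimates), estimate = unname(f@estimates),
               ci_low = unname(f@estimates - f@ci95[names(f@estimates)]),
               ci_high = unname(f@estimates + f@ci95[names(f@estimates)]),
               scenario = f@scenario, variant = f@variant, well_id = well)
  }
  tab <- if (is(fit, "MixedFit")) {
    rbind(rowsOf(fit@global, "global"),
          data.frame(name = "kbys", estimate = fit@wells$kbys,
                     ci_low = fit@wells$kbys - fit@wells$ci95,
                     ci_high = fit@wells$kbys + fit@wells$ci95,
                     scenario = "mixed", variant = fit@variant,
                     well_id = fit@wells$well_id))
  } else rowsOf(fit, "global")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
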