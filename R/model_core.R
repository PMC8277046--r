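#' State functions: glucose- and time-dependent fate weights
#'
#' The population's instantaneous fate is partitioned between starvation
#' death and proliferation by two complementary weights in \[0, 1\]:
#' \deqn{S_d(G, t) = \left(1 - \frac{G}{G + G_{min}}\right)\tanh(t), \qquad
#'       S_p(G, t) = 1 - S_d(G, t).}
#' The `tanh(t)` factor (t in days, 0 at medium change) delays the response
#' to the new glucose level: cells past the cell-cycle restriction point at
#' medium change divide regardless of the new medium, so the glucose effect
#' is not sensed at t = 0 and saturates within about two days.
#'
#' @param glucose glucose concentration, mM (vectorized, >= 0).
#' @param time days since medium change (vectorized, >= 0).
#' @param gmin minimum glucose level for proliferation, mM (> 0).
#' @return Numeric vector of weights; `stateDeath` in \[0, 1),
#'   `stateProlif = 1 - stateDeath` in (0, 1\].
#' @examples
#' stateDeath(5, time = 0, gmin = 0.1)        # 0: tanh(0) gates the response
#' stateDeath(0.1, time = 2, gmin = 0.1)      # 0.5 * tanh(2)
#' stateProlif(10, 1, 0.1) + stateDeath(10, 1, 0.1)  # identically 1
#' @export
stateDeath <- function(glucose, time, gmin) {
  if (any(glucose < 0) || any(time < 0) || any(gmin <= 0))
    stop("stateDeath requires glucose >= 0, time >= 0, gmin > 0")
  (1 - glucose / (glucose + gmin)) * tanh(time)
}

#' @rdname stateDeath
#' @export
stateProlif <- function(glucose, time, gmin) {
  1 - stateDeath(glucose, time, gmin)
}

checkVariant <- function(variant) {
  variant <- as.integer(variant)
  if (length(variant) != 1L || is.na(variant) || !variant %in% 1:3)
    stop("model variant must be 1 (no bystander), 2 (complete) or 3 (no starvation death)")
  variant
}

# Apply the variant mask: variant 1 drops the bystander terms, variant 3 the
# starvation-death terms, variant 2 keeps everything.
maskParams <- function(params, variant) {
  variant <- checkVariant(variant)
  if (variant == 1L) params@kbys <- 0
  if (variant == 3L) params@kd <- 0
  if (is.na(params@kbys))
    stop("kbys is unset; assign it (or choose variant 1) before simulating")
  params
}

#' Instantaneous rates of the growth model
#'
#' Right-hand side of the coupled system for live confluence N, dead
#' confluence D (both %) and glucose G (mM):
#' \deqn{dN/dt = k_p N (1 - N/\theta) S_p(G,t) - k_d N S_d(G,t)
#'              - k_{bys} N \frac{D}{D + N}}
#' \deqn{dD/dt = k_d N S_d(G,t) + k_{bys} N \frac{D}{D + N}}
#' \deqn{dG/dt = -v\, c\, N \frac{G}{G + G^*}}
#' with c = `cellsPerPct` converting confluence to cell count. Death only
#' moves mass from N to D, so `dN + dD` equals the logistic proliferation
#' term exactly. The dead-cell fraction `D/(D+N)` is defined as 0 in an
#' empty well (no cells, no bystander effect).
#'
#' @param n,d live and dead confluence, %.
#' @param glucose glucose, mM.
#' @param time days since medium change.
#' @param params a [KineticParams-class].
#' @param variant model variant: 1 drops the bystander terms, 3 drops the
#'   starvation-death terms, 2 is the complete model.
#' @return Named numeric: `dN`, `dD`, `dG` (per day).
#' @examples
#' p <- kineticParams(kp = 0.092, kd = 0.13, kbys = 0.2, v = 2.68e-5)
#' growthRates(n = 50, d = 0, glucose = 10, time = 1, params = p, variant = 2)
#' @export
growthRates <- function(n, d, glucose, time, params, variant = 2) {
  stopifnot(is(params, "KineticParams"))
  if (any(c(n, d, glucose, time) < 0))
    stop("state variables and time must be >= 0")
  p <- maskParams(params, variant)
  sd_ <- stateDeath(glucose, time, p@gmin)
  sp_ <- 1 - sd_
  fdead <- if (n + d > 0) d / (n + d) else 0
  grow <- p@kp * n * (1 - n / p@theta) * sp_
  starve <- p@kd * n * sd_
  byst <- p@kbys * n * fdead
  c(dN = grow - starve - byst,
    dD = starve + byst,
    dG = -p@v * p@cellsPerPct * n * glucose / (glucose + p@gstar))
}

#' Simulate a growth trajectory
#'
#' Integrates the model with an adaptive solver (compiled right-hand side,
#' via \pkg{deSolve}). Default method is the Dormand-Prince explicit
#' Runge-Kutta pair (`"ode45"`); tolerances are tight (rtol 1e-8, atol 1e-10)
#' so the structural invariants (non-negative states, non-increasing glucose)
#' hold to solver accuracy. Negative excursions within tolerance are clipped
#' to zero.
#'
#' @param n0,d0 initial live and dead confluence, %.
#' @param g0 initial glucose, mM.
#' @param params a [KineticParams-class].
#' @param variant model variant (see [growthRates()]).
#' @param times output grid, days; the first element is the initial time.
#' @param method deSolve integration method.
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `time_days`, `live_pct`, `dead_pct`,
#'   `glucose_mM`.
#' @examples
#' p <- kineticParams(kp = 0.092, kd = 0.13, kbys = 0.2, v = 2.68e-5)
#' traj <- simulateGrowth(30, 0.5, 2, p, times = seq(0, 4, 0.125))
#' head(traj)
#' @export
simulateGrowth <- function(n0, d0, g0, params, variant = 2,
                           times = seq(0, 4, by = 0.125),
                           method = "ode45", rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(params, "KineticParams"))
  if (any(c(n0, d0, g0) < 0)) stop("initial state must be >= 0")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  p <- maskParams(params, variant)
  parms <- c(p@kp, p@kd, p@kbys, p@v, p@theta, p@gstar, p@gmin, p@cellsPerPct)
  out <- deSolve::ode(y = c(N = n0, D = d0, G = g0), times = times,
                      func = "glucodyn_derivs", parms = parms,
                      dllname = "glucodyn", initfunc = "glucodyn_initmod",
                      method = method, rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    stop(sprintf("integration failed at t = %.4g days (last valid time)",
                 out[nrow(out), "time"]))
  }
  st <- out[, c("N", "D", "G"), drop = FALSE]
  # clip sub-tolerance negative excursions
  st[st < 0 & st > -1e-6] <- 0
  if (any(st < 0))
    stop("solver produced negative states beyond tolerance; reduce step tolerances")
  data.frame(time_days = out[, "time"], live_pct = st[, "N"],
             dead_pct = st[, "D"], glucose_mM = st[, "G"],
             row.names = NULL)
}

#' Relative contribution of each live-cell rate term
#'
#' Decomposes the live-cell equation at selected trajectory times into the
#' absolute magnitudes of its three terms — logistic proliferation,
#' starvation death and bystander death — each normalized by their sum.
#' Where all three terms vanish (e.g. an empty well) the contributions are
#' reported as `NA` and flagged in the `degenerate` column.
#'
#' @param trajectory data.frame as returned by [simulateGrowth()].
#' @param params the [KineticParams-class] used to produce the trajectory.
#' @param atTimes times (days) at which to report; defaults to days 0, 2, 4.
#'   Each must match a trajectory grid point.
#' @return data.frame with columns `time_days`, `logistic`, `starvation`,
#'   `bystander` (fractions summing to 1) and `degenerate`.
#' @export
termContributions <- function(trajectory, params, atTimes = c(0, 2, 4)) {
  stopifnot(is(params, "KineticParams"))
  idx <- match(atTimes, trajectory$time_days)
  if (any(is.na(idx)))
    stop("atTimes must be grid points of the trajectory")
  kbys <- if (is.na(params@kbys)) 0 else params@kbys
  res <- lapply(idx, function(i) {
    n <- trajectory$live_pct[i]; d <- trajectory$dead_pct[i]
    g <- trajectory$glucose_mM[i]; t <- trajectory$time_days[i]
    sd_ <- stateDeath(g, t, params@gmin)
    fdead <- if (n + d > 0) d / (n + d) else 0
    terms <- abs(c(logistic = params@kp * n * (1 - n / params@theta) * (1 - sd_),
                   starvation = params@kd * n * sd_,
                   bystander = kbys * n * fdead))
    tot <- sum(terms)
    if (tot == 0)
      data.frame(time_days = t, logistic = NA_real_, starvation = NA_real_,
                 bystander = NA_real_, degenerate = TRUE)
    else
      data.frame(time_days = t, logistic = terms[[1]] / tot,
                 starvation = terms[[2]] / tot, bystander = terms[[3]] / tot,
                 degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Write / read a single trajectory as CSV
#'
#' @param trajectory data.frame from [simulateGrowth()].
#' @param path file path.
#' @return `readTrajectory` returns the trajectory data.frame.
#' @export
writeTrajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("time_days", "live_pct", "dead_pct", "glucose_mM")
  if (!all(need %in% names(tr)))
    stop("trajectory file must have columns ", paste(need, collapse = ", "))
  tr[, need]
}
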