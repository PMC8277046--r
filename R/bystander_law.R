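# Dependence of the bystander death rate on initial conditions.
#
# After mixed calibration each well carries its own kbys estimate; this
# module quantifies how those estimates vary with seeding confluence N0 and
# initial glucose G0 (Pearson partial correlations) and condenses them into
# a cell-line law: a surface kbys0 * N0 * exp(-alpha * G0) when the rate
# scales with confluence, or a curve kbys0 * exp(-alpha * G0) + beta when it
# does not.

#' Evaluate a bystander law at initial conditions
#'
#' @param law a [BystanderLaw-class].
#' @param n0 initial confluence, % (ignored by the curve form).
#' @param g0 initial glucose, mM.
#' @return kbys, day^-1 (vectorized, non-negative).
#' @examples
#' law <- bystanderLaw("surface", kbys0 = 2.37e-5, alpha = 0.13)
#' evalLaw(law, n0 = 50, g0 = 5)   # 2.37e-5 * 50 * exp(-0.65)
#' @export
evalLaw <- function(law, n0 = NULL, g0) {
  stopifnot(is(law, "BystanderLaw"))
  if (any(g0 < 0)) stop("g0 must be >= 0")
  if (law@form == "surface") {
    if (is.null(n0) || any(is.na(n0))) stop("surface law requires n0")
    if (any(n0 < 0)) stop("n0 must be >= 0")
    law@kbys0 * n0 * exp(-law@alpha * g0)
  } else {
    law@kbys0 * exp(-law@alpha * g0) + law@beta
  }
}

#' First-order Pearson partial correlations of kbys with initial conditions
#'
#' Computes `r(kbys, N0 | G0)` and `r(kbys, G0 | N0)` with two-sided
#' p-values from the t distribution on n - 3 degrees of freedom.
#'
#' @param kbys per-well bystander rate estimates, day^-1.
#' @param n0 initial confluences, %.
#' @param g0 initial glucose levels, mM.
#' @return data.frame with columns `variable` (`"n0"`, `"g0"`), `partial_r`,
#'   `p_value`, `n`.
#' @export
partialCorrelation <- function(kbys, n0, g0) {
  n <- length(kbys)
  if (n < 4 || length(n0) != n || length(g0) != n)
    stop("need >= 4 aligned observations")
  if (stats::sd(n0) == 0 || stats::sd(g0) == 0 || stats::sd(kbys) == 0)
    stop("partial correlation undefined for constant variable")
  rkn <- stats::cor(kbys, n0); rkg <- stats::cor(kbys, g0); rng <- stats::cor(n0, g0)
  partial <- function(rxy, rxz, ryz)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- c(n0 = partial(rkn, rkg, rng), g0 = partial(rkg, rkn, rng))
  tstat <- r * sqrt((n - 3) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  data.frame(variable = names(r), partial_r = unname(r),
             p_value = unname(p), n = n, row.names = NULL)
}

# inverse-variance weights from CI half-widths; zero half-widths are capped
# at the smallest nonzero one (unit weights when all are zero/absent)
ciWeights <- function(ci, n) {
  if (is.null(ci) || all(is.na(ci)) || all(ci == 0)) return(rep(1, n))
  ci[is.na(ci)] <- 0
  ci[ci == 0] <- min(ci[ci > 0])
  1 / ci^2
}

lawCis <- function(resid, jac, names) {
  ci <- tryCatch(ciLinearized(resid, jac), error = function(e) {
    setNames(rep(NA_real_, length(names)), names)
  })
  setNames(as.numeric(ci)[seq_along(names)], names)
}

#' Fit the confluence-dependent bystander surface
#'
#' Weighted nonlinear least squares for `kbys = kbys0 * N0 * exp(-alpha *
#' G0)` with inverse-variance weights `1/ci^2`. Parameters enter a bounded
#' Levenberg-Marquardt solve initialized from the log-linear regression
#' `log(kbys) - log(N0) ~ G0`; 95% CIs are linearized from the weighted
#' Jacobian.
#'
#' @param samples data.frame with columns `n0`, `g0`, `kbys` and optionally
#'   `ci` (95% half-widths used as weights).
#' @return A [BystanderLaw-class] (surface form) with `ci95` filled.
#' @seealso [fitCurveLaw()], [generateLawSamples()]
#' @export
fitSurfaceLaw <- function(samples) {
  need <- c("n0", "g0", "kbys")
  if (!all(need %in% names(samples))) stop("samples need columns n0, g0, kbys")
  m <- nrow(samples)
  if (m < 3) stop("need >= 3 samples")
  if (length(unique(samples$g0)) < 2)
    stop("alpha non-identifiable: design has a single glucose level")
  if (length(unique(samples$n0)) < 2)
    stop("degenerate design: a single confluence level")
  w <- ciWeights(samples$ci, m)
  sw <- sqrt(w)
  pos <- samples$kbys > 0
  init <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(I(log(samples$kbys[pos]) - log(samples$n0[pos]))
                                ~ samples$g0[pos]))
    c(kbys0 = exp(cf[[1]]), alpha = max(-cf[[2]], 1e-6))
  } else c(kbys0 = max(samples$kbys) / max(samples$n0), alpha = 0.1)
  fn <- function(p) sw * (p[1] * samples$n0 * exp(-p[2] * samples$g0) - samples$kbys)
  jac <- function(p) {
    e <- exp(-p[2] * samples$g0)
    cbind(sw * samples$n0 * e, sw * -p[1] * samples$n0 * samples$g0 * e)
  }
  fit <- minpack.lm::nls.lm(par = init, fn = fn, jac = jac,
                            lower = c(0, 0), upper = c(Inf, Inf),
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-14, ptol = 1e-12, maxiter = 500))
  p <- fit$par
  ci <- lawCis(fn(p), jac(p), c("kbys0", "alpha"))
  flags <- character()
  if (p[[1]] <= 0) flags <- "flat-law degenerate fit (kbys0 at zero)"
  bystanderLaw("surface", kbys0 = p[[1]], alpha = p[[2]], ci95 = ci,
               flags = flags)
}

#' Fit the confluence-independent bystander curve
#'
#' Weighted nonlinear least squares for `kbys = kbys0 * exp(-alpha * G0) +
#' beta` (weights `1/ci^2`). Initialization: `beta` from the high-glucose
#' plateau, `kbys0` from the low-glucose excess, `alpha` from the log-linear
#' decay of the excess.
#'
#' @param samples data.frame with columns `g0`, `kbys` and optionally `ci`.
#' @return A [BystanderLaw-class] (curve form) with `ci95` filled; degenerate
#'   flat fits (no resolvable glucose dependence) are flagged.
#' @export
fitCurveLaw <- function(samples) {
  if (!all(c("g0", "kbys") %in% names(samples)))
    stop("samples need columns g0, kbys")
  m <- nrow(samples)
  if (m < 4) stop("need >= 4 samples")
  if (length(unique(samples$g0)) < 3)
    stop("alpha non-identifiable: need >= 3 glucose levels")
  w <- ciWeights(samples$ci, m)
  sw <- sqrt(w)
  ord <- order(samples$g0)
  hi <- samples$kbys[ord][max(1, m - 2):m]
  beta0 <- max(mean(hi), 0)
  excess <- pmax(samples$kbys - beta0, 0)
  amp0 <- max(max(excess), 1e-8)
  pos <- excess > amp0 * 1e-3
  alpha0 <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(excess[pos]) ~ samples$g0[pos]))
    max(-cf[[2]], 1e-3)
  } else 0.5
  fn <- function(p) sw * (p[1] * exp(-p[2] * samples$g0) + p[3] - samples$kbys)
  jac <- function(p) {
    e <- exp(-p[2] * samples$g0)
    cbind(sw * e, sw * -p[1] * samples$g0 * e, sw)
  }
  fit <- minpack.lm::nls.lm(par = c(kbys0 = amp0, alpha = alpha0, beta = beta0),
                            fn = fn, jac = jac, lower = c(0, 0, 0),
                            upper = rep(Inf, 3),
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-14, ptol = 1e-12, maxiter = 500))
  p <- fit$par
  ci <- lawCis(fn(p), jac(p), c("kbys0", "alpha", "beta"))
  flags <- character()
  span <- p[[1]] * (exp(-p[[2]] * min(samples$g0)) - exp(-p[[2]] * max(samples$g0)))
  if (span <= 1e-8 * max(p[[3]], max(samples$kbys)))
    flags <- "flat-law degenerate fit (no resolvable glucose dependence)"
  bystanderLaw("curve", kbys0 = p[[1]], alpha = p[[2]], beta = p[[3]],
               ci95 = ci, flags = flags)
}

#' Serialize a law to JSON (and back)
#'
#' @param law a [BystanderLaw-class].
#' @param path file path.
#' @return `readLaw` returns the [BystanderLaw-class].
#' @export
writeLaw <- function(law, path) {
  jsonlite::write_json(
    list(form = law@form, kbys0 = law@kbys0, alpha = law@alpha,
         beta = law@beta, ci95 = as.list(law@ci95), flags = law@flags),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname writeLaw
#' @export
readLaw <- function(path) {
  x <- jsonlite::read_json(path)
  nm <- if (x$form == "curve") c("kbys0", "alpha", "beta") else c("kbys0", "alpha")
  ci <- vapply(nm, function(k) {
    v <- x$ci95[[k]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  bystanderLaw(x$form, kbys0 = x$kbys0, alpha = x$alpha,
               beta = if (is.null(x$beta)) NA_real_ else as.numeric(x$beta),
               ci95 = ci, flags = as.character(unlist(x$flags)))
}
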