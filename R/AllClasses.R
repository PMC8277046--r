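#' @import methods
#' @importFrom stats setNames
#' @useDynLib glucodyn
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Kinetic parameters of the glucose-limited growth model
#'
#' Container for the calibratable rates and the fixed constants of the
#' three-species model (live confluence N, dead confluence D, glucose G).
#' Rates are per day; `v` is a per-cell glucose consumption rate on the
#' mM cell^-1 day^-1 scale and acts on the cell count `cellsPerPct * N`.
#'
#' @slot kp proliferation rate, day^-1.
#' @slot kd starvation (glucose-depletion) death rate, day^-1.
#' @slot kbys bystander death rate, day^-1; may be `NA` in profile objects
#'   where it is assigned per well from a [BystanderLaw-class].
#' @slot v glucose consumption rate, mM cell^-1 day^-1.
#' @slot theta carrying capacity, confluence %.
#' @slot gstar Michaelis-Menten constant of consumption, mM.
#' @slot gmin minimum glucose level for proliferation, mM.
#' @slot cellsPerPct cell count represented by one confluence percent
#'   (converts the confluence state to the cell count that `v` acts on).
#'
#' @seealso [kineticParams()], [growthRates()], [simulateGrowth()]
#' @export
setClass("KineticParams",
  representation(kp = "numeric", kd = "numeric", kbys = "numeric",
                 v = "numeric", theta = "numeric", gstar = "numeric",
                 gmin = "numeric", cellsPerPct = "numeric"),
  validity = function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && (is.na(x) || is.finite(x))
    for (s in slotNames(object))
      if (!one(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a single finite value", s))
    if (length(msg)) return(msg)
    vals <- c(kp = object@kp, kd = object@kd, kbys = object@kbys, v = object@v)
    bad <- names(vals)[!is.na(vals) & vals < 0]
    if (length(bad)) msg <- c(msg, paste("negative rate(s):", paste(bad, collapse = ", ")))
    pos <- c(theta = object@theta, gstar = object@gstar, gmin = object@gmin,
             cellsPerPct = object@cellsPerPct)
    bad <- names(pos)[is.na(pos) | pos <= 0]
    if (length(bad)) msg <- c(msg, paste("must be > 0:", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a KineticParams object
#'
#' @param kp,kd,kbys,v,theta,gstar,gmin,cellsPerPct see [KineticParams-class].
#'   `theta`, `gstar` and `gmin` default to 100 confluence %, 1 mM and 0.1 mM
#'   (literature-style stand-ins; the sources cited for them print no values),
#'   `cellsPerPct` to 1000 cells per confluence % (~1e5 cells in a confluent
#'   96-well well).
#' @return A [KineticParams-class] object.
#' @examples
#' kineticParams(kp = 0.092, kd = 0.13, kbys = 0.2, v = 2.68e-5)
#' @export
kineticParams <- function(kp, kd, kbys = NA_real_, v,
                          theta = 100, gstar = 1.0, gmin = 0.1,
                          cellsPerPct = 1000) {
  new("KineticParams", kp = as.numeric(kp), kd = as.numeric(kd),
      kbys = as.numeric(kbys), v = as.numeric(v), theta = as.numeric(theta),
      gstar = as.numeric(gstar), gmin = as.numeric(gmin),
      cellsPerPct = as.numeric(cellsPerPct))
}

setMethod("show", "KineticParams", function(object) {
  cat("KineticParams\n")
  cat(sprintf("  rates (day^-1): kp = %g, kd = %g, kbys = %g\n",
              object@kp, object@kd, object@kbys))
  cat(sprintf("  consumption v = %g mM cell^-1 day^-1 (x %g cells/%%)\n",
              object@v, object@cellsPerPct))
  cat(sprintf("  constants: theta = %g %%, G* = %g mM, Gmin = %g mM\n",
              object@theta, object@gstar, object@gmin))
})

#' Phenomenological bystander death-rate law
#'
#' Maps a well's initial conditions to its bystander death rate.
#' Two forms are supported:
#' \describe{
#'   \item{surface}{`kbys = kbys0 * N0 * exp(-alpha * G0)` — amplitude scales
#'     with initial confluence `N0` (%).}
#'   \item{curve}{`kbys = kbys0 * exp(-alpha * G0) + beta` — no confluence
#'     dependence; `beta` is a base death rate present at high glucose.}
#' }
#'
#' @slot form `"surface"` or `"curve"`.
#' @slot kbys0 amplitude (surface: day^-1 per confluence %; curve: day^-1).
#' @slot alpha glucose decay constant, mM^-1.
#' @slot beta base rate, day^-1 (`NA` for the surface form).
#' @slot ci95 named numeric of 95% CI half-widths (may be `NA`).
#' @slot flags character vector of fit diagnostics (e.g. non-identifiable
#'   `alpha` on a single-glucose design).
#' @seealso [bystanderLaw()], [evalLaw()], [fitSurfaceLaw()], [fitCurveLaw()]
#' @export
setClass("BystanderLaw",
  representation(form = "character", kbys0 = "numeric", alpha = "numeric",
                 beta = "numeric", ci95 = "numeric", flags = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@form %in% c("surface", "curve"))
      msg <- c(msg, "form must be 'surface' or 'curve'")
    if (!is.na(object@kbys0) && object@kbys0 < 0) msg <- c(msg, "kbys0 must be >= 0")
    if (!is.na(object@alpha) && object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    if (object@form == "curve" && is.na(object@beta))
      msg <- c(msg, "curve form requires beta")
    if (object@form == "surface" && !is.na(object@beta))
      msg <- c(msg, "surface form has no beta")
    if (!is.na(object@beta) && object@beta < 0) msg <- c(msg, "beta must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a BystanderLaw
#'
#' @param form `"surface"` or `"curve"`.
#' @param kbys0,alpha,beta law parameters (see [BystanderLaw-class]).
#' @param ci95 optional named numeric of 95% CI half-widths.
#' @param flags optional character vector of diagnostics.
#' @return A [BystanderLaw-class] object.
#' @examples
#' bystanderLaw("surface", kbys0 = 2.37e-5, alpha = 0.13)
#' @export
bystanderLaw <- function(form, kbys0, alpha, beta = NA_real_,
                         ci95 = NULL, flags = character()) {
  if (is.null(ci95)) {
    nm <- if (form == "curve") c("kbys0", "alpha", "beta") else c("kbys0", "alpha")
    ci95 <- setNames(rep(NA_real_, length(nm)), nm)
  }
  new("BystanderLaw", form = form, kbys0 = as.numeric(kbys0),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      ci95 = ci95, flags = flags)
}

setMethod("show", "BystanderLaw", function(object) {
  if (object@form == "surface") {
    cat(sprintf("BystanderLaw (surface): kbys = %g * N0 * exp(-%g * G0)\n",
                object@kbys0, object@alpha))
  } else {
    cat(sprintf("BystanderLaw (curve): kbys = %g * exp(-%g * G0) + %g\n",
                object@kbys0, object@alpha, object@beta))
  }
  if (any(!is.na(object@ci95)))
    cat("  ci95 half-widths:",
        paste(sprintf("%s = %.3g", names(object@ci95), object@ci95), collapse = ", "), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' Cell-line profile for the synthetic cohort generator
#'
#' Bundles the generating kinetic parameters (with `kbys` unset), the
#' bystander law used to assign per-well `kbys`, the relative noise levels of
#' the live and dead confluence readouts, and the seeding-confluence tiers.
#'
#' @slot name label of the emulated line.
#' @slot params [KineticParams-class] with `kbys = NA`.
#' @slot law [BystanderLaw-class] evaluated at each well's `(N0, G0)`.
#' @slot noiseLive,noiseDead relative (multiplicative Gaussian) noise, % of
#'   signal.
#' @slot tiers named numeric of seeding-confluence anchors, %.
#' @slot kbysJitter lognormal sd of per-well jitter on the law value.
#' @slot d0 mean initial dead confluence, %.
#' @seealso [btProfile()], [mdaProfile()], [generateCohort()]
#' @export
setClass("CellLineProfile",
  representation(name = "character", params = "KineticParams",
                 law = "BystanderLaw", noiseLive = "numeric",
                 noiseDead = "numeric", tiers = "numeric",
                 kbysJitter = "numeric", d0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@noiseLive < 0 || object@noiseDead < 0)
      msg <- c(msg, "noise levels must be >= 0")
    if (!length(object@tiers) || any(object@tiers <= 0))
      msg <- c(msg, "tiers must be positive confluences")
    if (object@d0 < 0) msg <- c(msg, "d0 must be >= 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CellLineProfile", function(object) {
  cat(sprintf("CellLineProfile '%s'\n", object@name))
  cat(sprintf("  noise (%% of signal): live %.2f, dead %.2f; tiers: %s %%\n",
              object@noiseLive, object@noiseDead,
              paste(round(object@tiers, 1), collapse = "/")))
  show(object@params)
  show(object@law)
})

#' Result of a nonlinear least-squares calibration
#'
#' @slot estimates named numeric point estimates of the free parameters.
#' @slot ci95 named numeric 95% CI half-widths (linearized).
#' @slot rss residual sum of squares, (confluence %)^2.
#' @slot residuals concatenated live+dead residual vector at the optimum.
#' @slot nobs number of fitted observations.
#' @slot scenario one of `"local"`, `"global"`, `"mixed"`.
#' @slot variant model variant id (1, 2 or 3).
#' @slot info list of fit diagnostics (multistart RSS values, convergence
#'   messages, seeds).
#' @seealso [fitPair()], [fitGlobal()], [fitMixed()]
#' @export
setClass("FitResult",
  representation(estimates = "numeric", ci95 = "numeric", rss = "numeric",
                 residuals = "numeric", nobs = "integer",
                 scenario = "character", variant = "integer", info = "list"),
  validity = function(object) {
    msg <- character()
    if (any(object@ci95 < 0, na.rm = TRUE)) msg <- c(msg, "ci95 must be >= 0")
    if (object@rss < 0) msg <- c(msg, "rss must be >= 0")
    if (!object@scenario %in% c("local", "global", "mixed"))
      msg <- c(msg, "scenario must be local/global/mixed")
    if (!object@variant %in% 1:3) msg <- c(msg, "variant must be 1, 2 or 3")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s scenario, model variant %d)\n",
              object@scenario, object@variant))
  tab <- data.frame(estimate = object@estimates,
                    ci95 = object@ci95[names(object@estimates)])
  print(signif(tab, 4))
  cat(sprintf("  RSS = %.6g over %d observations\n", object@rss, object@nobs))
})

#' Mixed-scenario calibration result
#'
#' Shared kinetic parameters for the cohort plus one bystander rate per well.
#'
#' @slot global [FitResult-class] for the shared parameters (their CIs come
#'   from the full joint Jacobian).
#' @slot wells data.frame with one row per well: `well_id`, `n0_pct`,
#'   `g0_mM`, `kbys`, `ci95`.
#' @slot rss pooled residual sum of squares.
#' @slot nobs total fitted observations.
#' @slot variant model variant id.
#' @seealso [fitMixed()]
#' @export
setClass("MixedFit",
  representation(global = "FitResult", wells = "data.frame", rss = "numeric",
                 nobs = "integer", variant = "integer"))

setMethod("show", "MixedFit", function(object) {
  cat(sprintf("MixedFit (model variant %d): %d wells, RSS = %.6g / %d obs\n",
              object@variant, nrow(object@wells), object@rss, object@nobs))
  cat("shared parameters:\n")
  tab <- data.frame(estimate = object@global@estimates,
                    ci95 = object@global@ci95[names(object@global@estimates)])
  print(signif(tab, 4))
  cat(sprintf("per-well kbys: median %.3g, range [%.3g, %.3g] day^-1\n",
              stats::median(object@wells$kbys), min(object@wells$kbys),
              max(object@wells$kbys)))
})

#' Monte-Carlo prediction band for one well
#'
#' Pointwise mean and 95% bounds of the live and dead confluence
#' trajectories under propagated parameter and initial-condition uncertainty.
#'
#' @slot times time grid, days.
#' @slot live,dead matrices with columns `mean`, `lo`, `hi` (confluence %).
#' @slot nDraws Monte-Carlo sample count.
#' @seealso [predictBand()], [bandAccuracy()]
#' @export
setClass("PredictionBand",
  representation(times = "numeric", live = "matrix", dead = "matrix",
                 nDraws = "integer"),
  validity = function(object) {
    msg <- character()
    for (nm in c("live", "dead")) {
      m <- slot(object, nm)
      if (!all(colnames(m) == c("mean", "lo", "hi")))
        msg <- c(msg, sprintf("%s must have columns mean/lo/hi", nm))
      else if (any(m[, "lo"] > m[, "mean"] + 1e-9) ||
               any(m[, "mean"] > m[, "hi"] + 1e-9))
        msg <- c(msg, sprintf("%s band must satisfy lo <= mean <= hi", nm))
      if (any(m < 0)) msg <- c(msg, sprintf("%s band must be >= 0", nm))
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PredictionBand", function(object) {
  cat(sprintf("PredictionBand: %d timepoints, %d draws\n",
              length(object@times), object@nDraws))
  i <- length(object@times)
  cat(sprintf("  day %.2f live %.1f [%.1f, %.1f] %%; dead %.1f [%.1f, %.1f] %%\n",
              object@times[i], object@live[i, "mean"], object@live[i, "lo"],
              object@live[i, "hi"], object@dead[i, "mean"],
              object@dead[i, "lo"], object@dead[i, "hi"]))
})
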