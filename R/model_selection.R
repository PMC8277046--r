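# Small-sample AICc model selection over (variant x scenario) candidates.

#' Corrected Akaike Information Criterion
#'
#' `AICc = n * ln(RSS) + 2p + 2p(p + 1) / (n - p - 1)`, the least-squares
#' form with the small-sample correction. Strictly increasing in both RSS
#' (at fixed n, p) and p (at fixed RSS, n).
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations entering the fit.
#' @param p number of free parameters.
#' @return The criterion value (lower is more parsimonious).
#' @examples
#' aicc(rss = 1, n = 100, p = 4)   # 8 + 40/95
#' @export
aicc <- function(rss, n, p) {
  if (any(rss <= 0)) stop("rss must be > 0")
  if (any(n <= p + 1)) stop("AICc undefined: need n > p + 1")
  n * log(rss) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Select the most parsimonious (variant, scenario) combination
#'
#' Runs the requested calibration for every candidate, tabulates pooled RSS,
#' observation count n (identical across candidates: all live and dead
#' points of every well), free-parameter count p (local: one set per well;
#' global: one shared set; mixed: shared set plus one `kbys` per well) and
#' AICc, and flags the minimum. Ties break toward smaller p, then candidate
#' order. Candidates whose calibration fails are flagged and skipped.
#'
#' @param cohort a [GrowthCohort-class].
#' @param candidates data.frame with columns `variant` (1-3) and `scenario`
#'   (`"local"`, `"global"`, `"mixed"`); defaults to all three variants
#'   under global sharing plus the bystander-capable variants under mixed
#'   sharing and the complete model fit locally.
#' @param config a [calibrationConfig()].
#' @param constants fixed model constants, see [fitPair()].
#' @return data.frame (one row per candidate): `variant`, `scenario`,
#'   `rss`, `n`, `p`, `aicc`, `failed`, `selected`.
#' @export
selectModel <- function(cohort,
                        candidates = data.frame(
                          variant = c(1, 2, 3, 2, 3, 2),
                          scenario = c("global", "global", "global",
                                       "mixed", "mixed", "local")),
                        config = calibrationConfig(),
                        constants = defaultConstants()) {
  if (nrow(candidates) < 2) stop("need >= 2 candidates")
  m <- nWells(cohort)
  # live + dead residuals per well; fits anchor at the second timepoint, so
  # the first observation of each series does not enter the residuals
  n <- 2L * (length(cohortTimes(cohort)) - 1L) * m
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    variant <- candidates$variant[i]
    scenario <- candidates$scenario[i]
    nfree <- length(freeParamNames(variant))
    res <- tryCatch({
      if (scenario == "global") {
        fit <- fitGlobal(cohort, variant, config, constants)
        list(rss = fit@rss, p = nfree)
      } else if (scenario == "mixed") {
        fit <- fitMixed(cohort, variant, config, constants)
        list(rss = fit@rss, p = (nfree - 1L) + m)
      } else if (scenario == "local") {
        rss <- sum(vapply(seq_len(m), function(j)
          fitPair(getPair(cohort, j), variant, config, constants,
                  computeCI = FALSE)@rss,
          numeric(1)))
        list(rss = rss, p = nfree * m)
      } else stop("unknown scenario: ", scenario)
    }, error = function(e) e)
    if (inherits(res, "error"))
      data.frame(variant = variant, scenario = scenario, rss = NA_real_,
                 n = n, p = NA_integer_, aicc = NA_real_, failed = TRUE)
    else
      data.frame(variant = variant, scenario = scenario, rss = res$rss,
                 n = n, p = res$p, aicc = aicc(res$rss, n, res$p),
                 failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!tab$failed)
  if (!length(ok)) stop("every candidate calibration failed")
  # minimum AICc; ties -> smaller p, then declaration order
  o <- ok[order(tab$aicc[ok], tab$p[ok], ok)]
  tab$selected <- seq_len(nrow(tab)) == o[1]
  tab
}
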