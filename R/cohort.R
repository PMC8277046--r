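#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' Cohort of live/dead confluence time courses
#'
#' A [SummarizedExperiment::SummarizedExperiment] specialization holding one
#' column per well and one row per timepoint, with two assays:
#' \describe{
#'   \item{live}{live-cell confluence, %.}
#'   \item{dead}{dead-cell confluence, %.}
#' }
#' `rowData` carries `time_days`; `colData` carries `well_id`, `replicate`,
#' `n0_pct` (seeding confluence) and `g0_mM` (initial glucose). Synthetic
#' cohorts additionally record the generating per-well bystander rate
#' (`true_kbys`) and the generator settings in `metadata()`.
#'
#' @seealso [generateCohort()], [readCohort()], [writeCohort()]
#' @export
setClass("GrowthCohort", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!all(c("live", "dead") %in% names(assays(object))))
      msg <- c(msg, "assays 'live' and 'dead' are required")
    need <- c("well_id", "replicate", "n0_pct", "g0_mM")
    if (!all(need %in% names(colData(object))))
      msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
    if (!"time_days" %in% names(rowData(object)))
      msg <- c(msg, "rowData must contain time_days")
    else {
      tt <- rowData(object)$time_days
      if (is.unsorted(tt, strictly = TRUE)) msg <- c(msg, "time_days must be strictly increasing")
    }
    if (length(msg) == 0) {
      if (any(assay(object, "live") < 0) || any(assay(object, "dead") < 0))
        msg <- c(msg, "confluence values must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Assemble a GrowthCohort from matrices
#'
#' @param times time grid, days (strictly increasing).
#' @param live,dead numeric matrices, `length(times)` rows x wells columns.
#' @param wells data.frame with per-well columns `well_id`, `replicate`,
#'   `n0_pct`, `g0_mM` (extra columns are kept).
#' @param metadata optional list recorded in the object metadata.
#' @return A [GrowthCohort-class].
#' @export
growthCohort <- function(times, live, dead, wells, metadata = list()) {
  live <- as.matrix(live); dead <- as.matrix(dead)
  stopifnot(nrow(live) == length(times), nrow(dead) == length(times),
            ncol(live) == nrow(wells), ncol(dead) == nrow(wells))
  colnames(live) <- colnames(dead) <- wells$well_id
  se <- SummarizedExperiment(
    assays = SimpleList(live = live, dead = dead),
    rowData = DataFrame(time_days = as.numeric(times)),
    colData = DataFrame(wells, row.names = wells$well_id))
  se@metadata <- metadata
  new("GrowthCohort", se)
}

#' Cohort accessors
#'
#' `cohortTimes` returns the time grid (days); `nWells` the number of wells;
#' `wellInfo` the per-well covariates as a data.frame; `getPair` one well's
#' live/dead time-course pair as a plain list.
#'
#' @param cohort a [GrowthCohort-class].
#' @param i well index or well id.
#' @return `getPair` returns `list(well_id, times, live, dead, n0, g0,
#'   replicate)`.
#' @export
cohortTimes <- function(cohort) rowData(cohort)$time_days

#' @rdname cohortTimes
#' @export
nWells <- function(cohort) ncol(cohort)

#' @rdname cohortTimes
#' @export
wellInfo <- function(cohort) as.data.frame(colData(cohort))

#' @rdname cohortTimes
#' @export
getPair <- function(cohort, i) {
  if (is.character(i)) i <- match(i, colData(cohort)$well_id)
  if (is.na(i) || i < 1 || i > ncol(cohort)) stop("unknown well")
  cd <- colData(cohort)
  list(well_id = cd$well_id[i],
       times = cohortTimes(cohort),
       live = as.numeric(assay(cohort, "live")[, i]),
       dead = as.numeric(assay(cohort, "dead")[, i]),
       n0 = cd$n0_pct[i], g0 = cd$g0_mM[i],
       replicate = cd$replicate[i])
}

setMethod("show", "GrowthCohort", function(object) {
  cd <- colData(object)
  cat(sprintf("GrowthCohort: %d wells x %d timepoints (%.3g to %.3g days)\n",
              ncol(object), nrow(object), min(cohortTimes(object)),
              max(cohortTimes(object))))
  cat(sprintf("  glucose levels (mM): %s\n",
              paste(sort(unique(cd$g0_mM)), collapse = ", ")))
  cat(sprintf("  seeding confluence (%%): %.1f to %.1f; replicates per condition: %d\n",
              min(cd$n0_pct), max(cd$n0_pct), max(cd$replicate)))
  md <- metadata(object)
  if (!is.null(md$profile)) cat(sprintf("  generated from profile '%s' (seed %s)\n",
                                        md$profile, md$seed))
})
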