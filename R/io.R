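# Delimited-text interchange for cohorts: long-format CSV (one row per well
# and timepoint) plus an optional JSON manifest with generator provenance.

cohortColumns <- c("well_id", "replicate", "n0_pct", "g0_mM", "time_days",
                   "live_pct", "dead_pct")

#' Write / read a cohort as long-format CSV
#'
#' Columns: `well_id`, `replicate`, `n0_pct`, `g0_mM`, `time_days`,
#' `live_pct`, `dead_pct`. `writeCohort` also writes `<path>.json` with the
#' cohort metadata (profile, design, seed) when present. `readCohort`
#' validates the schema and reports offending wells and rows: every well
#' must have strictly increasing times on a common grid and non-negative
#' confluences.
#'
#' @param cohort a [GrowthCohort-class].
#' @param path CSV file path.
#' @param manifest write the JSON manifest next to the CSV?
#' @return `readCohort` returns a [GrowthCohort-class]; `writeCohort` the
#'   path, invisibly.
#' @export
writeCohort <- function(cohort, path, manifest = TRUE) {
  info <- wellInfo(cohort)
  times <- cohortTimes(cohort)
  m <- nWells(cohort)
  long <- data.frame(
    well_id = rep(info$well_id, each = length(times)),
    replicate = rep(info$replicate, each = length(times)),
    n0_pct = rep(info$n0_pct, each = length(times)),
    g0_mM = rep(info$g0_mM, each = length(times)),
    time_days = rep(times, m),
    live_pct = as.vector(assay(cohort, "live")),
    dead_pct = as.vector(assay(cohort, "dead")))
  utils::write.csv(long, path, row.names = FALSE)
  md <- metadata(cohort)
  if (manifest && length(md))
    jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  long <- utils::read.csv(path)
  missing <- setdiff(cohortColumns, names(long))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(bad <- long$live_pct < 0 | long$dead_pct < 0)) {
    i <- which(bad)[1]
    stop(sprintf("negative confluence in well %s (row %d)", long$well_id[i], i))
  }
  ids <- unique(long$well_id)
  times <- long$time_days[long$well_id == ids[1]]
  if (is.unsorted(times, strictly = TRUE)) {
    stop(sprintf("non-monotone times within well %s", ids[1]))
  }
  live <- dead <- matrix(NA_real_, length(times), length(ids))
  wells <- data.frame(well_id = ids, replicate = NA_integer_,
                      n0_pct = NA_real_, g0_mM = NA_real_)
  for (k in seq_along(ids)) {
    rows <- which(long$well_id == ids[k])
    tt <- long$time_days[rows]
    if (is.unsorted(tt, strictly = TRUE))
      stop(sprintf("non-monotone times within well %s (rows %d..%d)",
                   ids[k], rows[1], rows[length(rows)]))
    if (length(tt) != length(times) || any(abs(tt - times) > 1e-9))
      stop(sprintf("well %s is not on the common time grid", ids[k]))
    live[, k] <- long$live_pct[rows]
    dead[, k] <- long$dead_pct[rows]
    wells$replicate[k] <- long$replicate[rows[1]]
    wells$n0_pct[k] <- long$n0_pct[rows[1]]
    wells$g0_mM[k] <- long$g0_mM[rows[1]]
  }
  md <- list()
  mpath <- paste0(path, ".json")
  if (file.exists(mpath)) md <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  growthCohort(times, live, dead, wells, metadata = md)
}
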