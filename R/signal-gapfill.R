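# Gap filling.
#
# For a feature missing in a sample, the retention-time window is predicted
# by the sample's own detected features: each detected feature proposes an
# offset between its in-sample apex and the consensus retention time, and
# the predictor whose offset best predicts the other detected features'
# apexes (lowest mean absolute cross-prediction error) wins. The raw map
# intensity is then integrated over the predicted window within the m/z
# tolerance.

#' Fill missing feature-table cells from the raw maps
#'
#' @param table A `feature_table` from [align_samples()].
#' @param maps Named list of the samples' raw (or baseline-corrected)
#'   `scan_map`s, names matching the table's sample columns.
#' @param mz_tol Absolute m/z tolerance, Da.
#' @param ppm Relative tolerance, ppm (larger applies).
#' @return The table with missing cells integrated and flagged
#'   `"gap-filled"`; detected cells are never overwritten. Cells with no
#'   signal in the predicted window are filled with 0.
#' @export
fill_gaps <- function(table, maps, mz_tol = 0.025, ppm = 50) {
  stopifnot(inherits(table, "feature_table"))
  samples <- colnames(table$intensity)
  stopifnot(all(samples %in% names(maps)))
  tol_at <- function(mz) max(mz_tol, ppm * 1e-6 * mz)
  feat <- table$features
  for (s in samples) {
    missing_rows <- which(table$provenance[, s] == "missing")
    if (!length(missing_rows)) next
    det <- which(table$provenance[, s] == "detected")
    offset <- 0
    if (length(det) >= 2) {
      offs <- table$rt_raw[det, s] - feat$rt[det]
      errs <- vapply(seq_along(det), function(k) {
        mean(abs((feat$rt[det[-k]] + offs[k]) - table$rt_raw[det[-k], s]))
      }, 0)
      offset <- offs[which.min(errs)]
    } else if (length(det) == 1) {
      offset <- table$rt_raw[det, s] - feat$rt[det]
    }
    cen <- maps[[s]]$centroids
    tmin <- maps[[s]]$scan_times
    for (r in missing_rows) {
      lo <- feat$fwqm_lo[r] + offset - 0.05
      hi <- feat$fwqm_hi[r] + offset + 0.05
      mz0 <- feat$mean_mz[r]
      tol <- tol_at(mz0)
      sel <- cen[abs(cen$mz - mz0) <= tol, ]
      sel <- sel[tmin[sel$scan] >= lo & tmin[sel$scan] <= hi, ]
      val <- 0
      if (nrow(sel)) {
        eic <- tapply(sel$intensity, sel$scan, sum)
        scans <- as.integer(names(eic))
        o <- order(scans)
        scans <- scans[o]; eic <- eic[o]
        if (length(scans) >= 2) {
          tt <- tmin[scans] * 60
          val <- sum(diff(tt) * (head(eic, -1) + tail(eic, -1)) / 2)
        } else {
          val <- eic[[1]] * 60 / length(tmin) # single point: nominal dwell
        }
      }
      table$intensity[r, s] <- val
      table$provenance[r, s] <- "gap-filled"
    }
  }
  table
}
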