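# 2D windowed-quantile baseline correction.
#
# The acquisition plane is tiled with half-open cells of 0.01 Da x 1.5 min;
# each cell's background is estimated as the 40% quantile of the
# intensities observed in it. Scans contributing no centroid to a cell
# count as implicit zeros, so sparse cells (a lone chromatographic peak
# occupying a small fraction of the retention window) are not docked their
# own signal, while persistent background present at every scan is removed
# in full.

#' Correct a scan map's baseline
#'
#' @param map A `scan_map`.
#' @param mz_window Cell width in m/z, Da.
#' @param rt_window Cell width in retention time, minutes.
#' @param quantile Background quantile in (0, 1).
#' @return The corrected `scan_map` (intensities reduced by their cell's
#'   estimate and clamped at zero; zero-intensity centroids dropped). The
#'   attribute `baseline_corrected` is set.
#' @export
correct_baseline <- function(map, mz_window = 0.01, rt_window = 1.5,
                             quantile = 0.40) {
  stopifnot(inherits(map, "scan_map"), quantile > 0, quantile < 1)
  cen <- map$centroids
  if (!nrow(cen)) {
    warning("empty scan map; baseline correction is a no-op")
    attr(map, "baseline_corrected") <- TRUE
    return(map)
  }
  times <- map$scan_times
  # half-open [lo, hi) cells in both axes
  mz_cell <- floor(cen$mz / mz_window)
  rt_cell <- floor(times[cen$scan] / rt_window)
  # scans available per rt slab (implicit zeros for absent scans)
  slab_scans <- table(floor(times / rt_window))
  key <- paste(mz_cell, rt_cell)
  spl <- split(seq_len(nrow(cen)), key)
  corrected <- cen$intensity
  for (k in names(spl)) {
    idx <- spl[[k]]
    rt_k <- sub("^\\S+ ", "", k)
    n_total <- slab_scans[[rt_k]]
    v <- cen$intensity[idx]
    if (length(v) < n_total) v <- c(v, rep(0, n_total - length(v)))
    q <- stats::quantile(v, probs = quantile, names = FALSE)
    corrected[idx] <- pmax(cen$intensity[idx] - q, 0)
  }
  out <- data.table::copy(cen)
  out$intensity <- corrected
  out <- out[out$intensity > 0, ]
  res <- scan_map(map$scan_times, out, map$acq)
  attr(res, "baseline_corrected") <- TRUE
  res
}
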