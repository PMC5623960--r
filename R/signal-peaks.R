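# Grid-based chromatographic peak detection.
#
# A parameter-faithful simplified re-implementation of grid peak picking on
# centroided maps: centroids are clustered along m/z (gap splitting at the
# m/z tolerance), each cluster's extracted-ion chromatogram is smoothed over
# the smoothing window, local maxima above the minimum height become peak
# apexes, and flanks are walked outward under the intensity-similarity
# constraint. Areas are trapezoidal integrals of the raw trace over the
# full peak extent (counts x seconds); the full-width-at-quarter-maximum
# (FWQM) window is recorded for downstream trace correlation.

.moving_avg <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2)) -> y
  # fill filter NAs at the edges with partial means
  n <- length(x)
  half <- (w - 1) %/% 2
  for (i in which(is.na(y))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    y[i] <- mean(x[lo:hi])
  }
  y
}

#' Detect chromatographic peaks in a scan map
#'
#' @param map A (baseline-corrected) `scan_map`.
#' @param min_height Minimum apex intensity, counts.
#' @param mz_tol m/z clustering tolerance, Da.
#' @param rt_min,rt_max Allowed peak duration window, minutes.
#' @param smoothing Smoothing time, minutes.
#' @param similarity Minimum allowed intensity ratio between consecutive
#'   scans along a peak flank (flank walking stops when the smoothed signal
#'   drops faster than this, rises again, or reaches the floor).
#' @param sample_id Identifier stored on each feature.
#' @return A `peak_features` data frame: one row per feature with columns
#'   `feature_id`, `sample_id`, `mean_mz`, `mz_sd`, `rt_apex`,
#'   `apex_intensity`, `fwqm_lo`, `fwqm_hi`, `rt_lo`, `rt_hi`, `area`,
#'   `charge`, `is_monoisotopic`, and a `trace` list column of per-scan
#'   `(time, intensity)` within the FWQM bounds.
#' @export
detect_peaks <- function(map, min_height = 1000, mz_tol = 0.05,
                         rt_min = 0.1, rt_max = 2.5, smoothing = 0.1,
                         similarity = 0.5, sample_id = "S1") {
  stopifnot(inherits(map, "scan_map"))
  cen <- map$centroids
  times <- map$scan_times
  nscan <- length(times)
  empty <- data.frame(feature_id = character(), sample_id = character(),
                      mean_mz = numeric(), mz_sd = numeric(),
                      rt_apex = numeric(), apex_intensity = numeric(),
                      fwqm_lo = numeric(), fwqm_hi = numeric(),
                      rt_lo = numeric(), rt_hi = numeric(),
                      area = numeric(), charge = integer(),
                      is_monoisotopic = logical())
  empty$trace <- list()
  class(empty) <- c("peak_features", "data.frame")
  if (!nrow(cen)) return(empty)

  dt_s <- mean(diff(times)) * 60
  w <- max(1L, round(smoothing * 60 / dt_s))

  ord <- order(cen$mz)
  mz_sorted <- cen$mz[ord]
  gaps <- which(diff(mz_sorted) > mz_tol)
  cluster_of_sorted <- rep(seq_len(length(gaps) + 1L),
                           diff(c(0L, gaps, length(mz_sorted))))
  cluster <- integer(nrow(cen))
  cluster[ord] <- cluster_of_sorted

  feats <- list()
  fid <- 0L
  for (cl in split(seq_len(nrow(cen)), cluster)) {
    sub <- cen[cl, ]
    eic <- rep(0, nscan)
    agg <- tapply(sub$intensity, sub$scan, sum)
    eic[as.integer(names(agg))] <- agg
    sm <- .moving_avg(eic, w)
    used <- rep(FALSE, nscan)
    repeat {
      cand <- which(!used & sm >= min_height)
      if (!length(cand)) break
      apex <- cand[which.max(sm[cand])]
      floor_i <- max(sm[apex] * 0.005, 0.5)
      walk <- function(dir) {
        i <- apex
        repeat {
          j <- i + dir
          if (j < 1 || j > nscan || used[j]) break
          if (sm[j] > sm[i] * 1.02) break              # rising: next peak
          if (sm[i] > 0 && sm[j] / sm[i] < similarity &&
              sm[j] < sm[apex] / 4) break              # similarity cut-off
          i <- j
          if (sm[i] <= floor_i) break
        }
        i
      }
      lo <- walk(-1L); hi <- walk(1L)
      span <- lo:hi
      used[span] <- TRUE
      dur <- times[hi] - times[lo]
      if (dur < rt_min || dur > rt_max) next
      if (max(eic[span]) < min_height) next
      # FWQM bounds around the apex
      qlim <- sm[apex] / 4
      f_lo <- apex; while (f_lo > lo && sm[f_lo - 1] >= qlim) f_lo <- f_lo - 1
      f_hi <- apex; while (f_hi < hi && sm[f_hi + 1] >= qlim) f_hi <- f_hi + 1
      raw_apex <- span[which.max(eic[span])]
      in_span <- sub$scan %in% span
      wts <- sub$intensity[in_span]
      mzs <- sub$mz[in_span]
      mmz <- sum(mzs * wts) / sum(wts)
      msd <- sqrt(sum(wts * (mzs - mmz)^2) / sum(wts))
      msd <- max(msd, 1e-4)
      area <- sum(diff(times[span] * 60) *
                    (head(eic[span], -1) + tail(eic[span], -1)) / 2)
      fid <- fid + 1L
      tr <- data.frame(time = times[f_lo:f_hi], intensity = eic[f_lo:f_hi])
      feats[[fid]] <- data.frame(
        feature_id = sprintf("%s_F%04d", sample_id, fid),
        sample_id = sample_id,
        mean_mz = mmz, mz_sd = msd,
        rt_apex = times[raw_apex],
        apex_intensity = eic[raw_apex],
        fwqm_lo = times[f_lo], fwqm_hi = times[f_hi],
        rt_lo = times[lo], rt_hi = times[hi],
        area = area, charge = NA_integer_, is_monoisotopic = NA,
        stringsAsFactors = FALSE
      )
      feats[[fid]]$trace <- list(tr)
    }
  }
  if (!length(feats)) return(empty)
  out <- do.call(rbind, feats)
  out <- out[order(out$mean_mz, out$rt_apex), ]
  rownames(out) <- NULL
  class(out) <- c("peak_features", "data.frame")
  out
}
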