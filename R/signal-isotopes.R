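# Isotopologue grouping.
#
# Envelope members are chained at a spacing of 1.00336/z Da (z in {1, 2}),
# co-eluting within the retention-time tolerance, with apex intensities
# monotonically non-increasing along the chain; the lowest-m/z member is
# the representative (monoisotopic) feature.

#' Group isotopologue features
#'
#' @param features A `peak_features` table.
#' @param mz_tol Absolute m/z tolerance, Da.
#' @param ppm Relative tolerance, ppm (the larger of the two applies).
#' @param rt_tol Apex retention-time tolerance, minutes.
#' @param max_charge Maximum charge state considered.
#' @return The table with `charge` and `is_monoisotopic` set and a new
#'   `isotope_group` column; non-monoisotopic members carry
#'   `is_monoisotopic = FALSE` and should be excluded downstream (see
#'   [monoisotopic_features()]).
#' @export
group_isotopes <- function(features, mz_tol = 0.001, ppm = 10,
                           rt_tol = 0.25, max_charge = 2L) {
  f <- features
  n <- nrow(f)
  if (!n) return(f)
  ord <- order(f$mean_mz)
  assigned <- rep(FALSE, n)
  f$charge <- rep(NA_integer_, n)
  f$is_monoisotopic <- rep(NA, n)
  f$isotope_group <- rep(NA_integer_, n)
  gid <- 0L
  tol_at <- function(mz) max(mz_tol, ppm * 1e-6 * mz)
  for (i in ord) {
    if (assigned[i]) next
    best_chain <- i
    best_z <- 1L
    for (z in seq_len(max_charge)) {
      chain <- i
      repeat {
        last <- chain[length(chain)]
        target <- f$mean_mz[last] + .C13_DELTA / z
        cand <- which(!assigned &
                        abs(f$mean_mz - target) <= tol_at(target) &
                        abs(f$rt_apex - f$rt_apex[i]) <= rt_tol &
                        f$apex_intensity <= f$apex_intensity[last])
        cand <- setdiff(cand, chain)
        if (!length(cand)) break
        nxt <- cand[which.min(abs(f$mean_mz[cand] - target))]
        chain <- c(chain, nxt)
      }
      if (length(chain) > length(best_chain)) {
        best_chain <- chain
        best_z <- z
      }
    }
    gid <- gid + 1L
    assigned[best_chain] <- TRUE
    f$charge[best_chain] <- best_z
    f$is_monoisotopic[best_chain] <- FALSE
    f$is_monoisotopic[best_chain[1]] <- TRUE
    f$isotope_group[best_chain] <- gid
  }
  f
}

#' Keep only monoisotopic representatives
#'
#' @param features A `peak_features` table processed by [group_isotopes()].
#' @return The monoisotopic subset.
#' @export
monoisotopic_features <- function(features) {
  out <- features[isTRUE_vec(features$is_monoisotopic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
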