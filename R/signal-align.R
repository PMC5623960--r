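# Retention-time alignment by random-sample consensus.
#
# Candidate matches between each sample and the reference (the sample with
# most features) are gathered within the pre-correction tolerances; RANSAC
# fits a monotone retention-time correction (linear consensus model,
# refined by a monotone loess on the inliers), and features are merged
# across samples within the post-correction tolerances. Consensus m/z is
# the intensity-weighted mean; row-identity ties break toward the highest
# summed intensity.

.rt_correction_fit <- function(rt_sample, rt_ref, inlier_threshold,
                               min_inliers, iterations, rng) {
  n <- length(rt_sample)
  if (n < 2) return(NULL)
  best <- NULL
  best_n <- 0L
  for (it in seq_len(iterations)) {
    pick <- ceiling(rng(2) * n)
    if (pick[1] == pick[2]) next
    dx <- rt_sample[pick[2]] - rt_sample[pick[1]]
    if (abs(dx) < 1e-9) next
    b <- (rt_ref[pick[2]] - rt_ref[pick[1]]) / dx
    if (b <= 0.5 || b >= 2) next
    a <- rt_ref[pick[1]] - b * rt_sample[pick[1]]
    resid <- abs(a + b * rt_sample - rt_ref)
    inl <- resid < inlier_threshold
    if (sum(inl) > best_n) {
      best_n <- sum(inl)
      best <- list(a = a, b = b, inliers = inl)
    }
  }
  if (is.null(best) || best_n < max(2, min_inliers * n)) return(NULL)
  xs <- rt_sample[best$inliers]
  ys <- rt_ref[best$inliers]
  model <- if (length(unique(xs)) >= 6) {
    lo <- stats::loess(ys ~ xs, span = 0.75, degree = 1)
    grid <- seq(min(xs), max(xs), length.out = 64)
    pred <- predict(lo, grid)
    pred <- cummax(pred)  # enforce monotonicity
    function(x) {
      y <- approx(grid, pred, xout = x, rule = 2)$y
      # extend linearly outside the fitted range with the consensus slope
      out_lo <- x < grid[1]; out_hi <- x > grid[length(grid)]
      y[out_lo] <- pred[1] + best$b * (x[out_lo] - grid[1])
      y[out_hi] <- pred[length(pred)] + best$b * (x[out_hi] - grid[length(grid)])
      y
    }
  } else {
    function(x) best$a + best$b * x
  }
  list(map = model, n_inliers = best_n, n_candidates = n,
       slope = best$b, offset = best$a)
}

#' Align features across samples into a feature table
#'
#' @param features_list Named list of `peak_features` tables (>= 2 samples;
#'   typically [monoisotopic_features()] output).
#' @param mz_tol Absolute m/z match tolerance, Da.
#' @param ppm Relative tolerance, ppm (larger of the two applies).
#' @param rt_tol_before Retention-time tolerance before correction, minutes.
#' @param rt_tol_after Tolerance after correction, minutes.
#' @param min_inliers Minimum inlier fraction for a valid consensus model.
#' @param inlier_threshold RANSAC inlier residual threshold, minutes.
#' @param iterations RANSAC iterations.
#' @param seed Integer seed for the RANSAC sampler.
#' @return A `feature_table` list: `features` (consensus `feature_id`,
#'   `mean_mz`, `rt`, `fwqm_lo`, `fwqm_hi`), `intensity` and `provenance`
#'   (feature x sample matrices; provenance in {detected, missing}), `rt`
#'   (per-sample corrected apex times), `rt_raw` (uncorrected),
#'   `corrections` (per-sample diagnostics).
#' @export
align_samples <- function(features_list, mz_tol = 0.025, ppm = 50,
                          rt_tol_before = 2, rt_tol_after = 1.5,
                          min_inliers = 0.25, inlier_threshold = 1,
                          iterations = 1000L, seed = 1L) {
  stopifnot(length(features_list) >= 2)
  if (is.null(names(features_list)))
    names(features_list) <- paste0("S", seq_along(features_list))
  samples <- names(features_list)
  tol_at <- function(mz) pmax(mz_tol, ppm * 1e-6 * mz)

  ref_i <- which.max(vapply(features_list, nrow, 0L))
  ref <- features_list[[ref_i]]
  rng <- .rng_stream(seed, "ransac")

  corrections <- list()
  corrected <- list()
  for (s in samples) {
    f <- features_list[[s]]
    f$rt_corrected <- f$rt_apex
    if (s != samples[ref_i] && nrow(f) && nrow(ref)) {
      # candidate matches within pre-correction tolerances
      cand <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
        j <- which(abs(ref$mean_mz - f$mean_mz[i]) <=
                     tol_at(f$mean_mz[i]) &
                   abs(ref$rt_apex - f$rt_apex[i]) <= rt_tol_before)
        if (!length(j)) return(NULL)
        j <- j[which.min(abs(ref$rt_apex[j] - f$rt_apex[i]))]
        data.frame(rs = f$rt_apex[i], rr = ref$rt_apex[j])
      }))
      fit <- if (!is.null(cand))
        .rt_correction_fit(cand$rs, cand$rr, inlier_threshold,
                           min_inliers, iterations, rng) else NULL
      if (is.null(fit)) {
        warning("sample ", s, ": insufficient RANSAC support; ",
                "falling back to identity RT correction")
        corrections[[s]] <- list(identity = TRUE)
      } else {
        f$rt_corrected <- fit$map(f$rt_apex)
        corrections[[s]] <- c(fit[c("n_inliers", "n_candidates",
                                    "slope", "offset")],
                              list(identity = FALSE))
      }
    } else {
      corrections[[s]] <- list(identity = TRUE)
    }
    corrected[[s]] <- f
  }

  pool <- do.call(rbind, lapply(samples, function(s) {
    f <- corrected[[s]]
    if (!nrow(f)) return(NULL)
    data.frame(sample = s, idx = seq_len(nrow(f)), mz = f$mean_mz,
               rt = f$rt_corrected, rt_raw = f$rt_apex, area = f$area,
               apex = f$apex_intensity,
               fwqm_lo = f$fwqm_lo, fwqm_hi = f$fwqm_hi,
               stringsAsFactors = FALSE)
  }))
  pool <- pool[order(pool$mz, pool$rt), ]
  # greedy clustering within post-correction tolerances
  cluster <- integer(nrow(pool))
  cid <- 0L
  for (i in seq_len(nrow(pool))) {
    if (cluster[i]) next
    cid <- cid + 1L
    members <- i
    for (j in seq_len(nrow(pool))[-i]) {
      if (cluster[j]) next
      if (abs(pool$mz[j] - pool$mz[i]) <= tol_at(pool$mz[i]) &&
          abs(pool$rt[j] - pool$rt[i]) <= rt_tol_after &&
          !(pool$sample[j] %in% pool$sample[members])) {
        members <- c(members, j)
      }
    }
    cluster[members] <- cid
  }
  ncl <- cid
  nfeat <- ncl
  intensity <- matrix(NA_real_, nfeat, length(samples),
                      dimnames = list(NULL, samples))
  rt_mat <- matrix(NA_real_, nfeat, length(samples),
                   dimnames = list(NULL, samples))
  rt_raw_mat <- rt_mat
  feat <- data.frame(feature_id = character(nfeat), mean_mz = numeric(nfeat),
                     rt = numeric(nfeat), fwqm_lo = numeric(nfeat),
                     fwqm_hi = numeric(nfeat), stringsAsFactors = FALSE)
  for (c0 in seq_len(ncl)) {
    m <- pool[cluster == c0, ]
    wt <- m$apex
    feat$mean_mz[c0] <- sum(m$mz * wt) / sum(wt)
    feat$rt[c0] <- sum(m$rt * wt) / sum(wt)
    feat$fwqm_lo[c0] <- mean(m$fwqm_lo + (m$rt - m$rt_raw))
    feat$fwqm_hi[c0] <- mean(m$fwqm_hi + (m$rt - m$rt_raw))
    intensity[c0, m$sample] <- m$area
    rt_mat[c0, m$sample] <- m$rt
    rt_raw_mat[c0, m$sample] <- m$rt_raw
  }
  feat$feature_id <- sprintf("FT%04d", seq_len(nfeat))
  ord <- order(feat$mean_mz, feat$rt)
  feat <- feat[ord, ]; intensity <- intensity[ord, , drop = FALSE]
  rt_mat <- rt_mat[ord, , drop = FALSE]
  rt_raw_mat <- rt_raw_mat[ord, , drop = FALSE]
  rownames(feat) <- NULL
  provenance <- ifelse(is.na(intensity), "missing", "detected")
  structure(list(features = feat, intensity = intensity,
                 provenance = provenance, rt = rt_mat, rt_raw = rt_raw_mat,
                 corrections = corrections),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%d gap-filled)\n",
              nrow(x$intensity), ncol(x$intensity),
              sum(x$provenance == "gap-filled")))
  invisible(x)
}
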