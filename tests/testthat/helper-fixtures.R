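# Shared fixtures, all built in code.

# a short, lightweight acquisition window covering the acetogenin region
test_acq <- function(noise_sd = 0, baseline_amplitude = 0,
                     gradient_length = 24, mz_max = 900) {
  acquisition_settings(mz_min = 150, mz_max = mz_max,
                       gradient_length = gradient_length,
                       noise_sd = noise_sd,
                       baseline_amplitude = baseline_amplitude)
}

# noise-free mesocarp simulation used by several signal tests
sim_noise_free <- function(seed = 1, dropout_p = 0, rt_shift = 0) {
  db <- generate_lipid_db(1)
  prof <- generate_sample_profile("mesocarp", "unripe", seed = seed,
                                  noise_cv = 0)
  synthesize_scan_map(prof, db, test_acq(), seed = seed,
                      dropout_p = dropout_p, rt_shift = rt_shift)
}

# ledger rows a detector run on test_acq() can be held accountable for
usable_ledger <- function(ledger, min_height = 1000) {
  ledger[!ledger$skipped_out_of_range & !ledger$rt_truncated &
           ledger$apex_intensity >= min_height, ]
}

# match one detected feature to a ledger row; NA if not exactly one match
match_ledger_area <- function(features, led_row,
                              mz_tol = 0.05, rt_tol = 0.3) {
  j <- which(abs(features$mean_mz - led_row$mz) < mz_tol &
               abs(features$rt_apex - led_row$rt_center) < rt_tol)
  if (length(j) != 1) return(NA_real_)
  features$area[j] / led_row$area
}

# fabricate a minimal peak_features row with a supplied trace
make_feature <- function(id, mz, rt, apex, fwqm_lo, fwqm_hi, trace,
                         mz_sd = 0.002, area = NULL) {
  tr <- trace
  f <- data.frame(feature_id = id, sample_id = "T", mean_mz = mz,
                  mz_sd = mz_sd, rt_apex = rt, apex_intensity = apex,
                  fwqm_lo = fwqm_lo, fwqm_hi = fwqm_hi,
                  rt_lo = fwqm_lo, rt_hi = fwqm_hi,
                  area = area %||% sum(tr$intensity),
                  charge = 1L, is_monoisotopic = TRUE,
                  stringsAsFactors = FALSE)
  f$trace <- list(tr)
  class(f) <- c("peak_features", "data.frame")
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian trace sampled on the instrument scan grid over the FWQM window
gaussian_trace <- function(center_min, fwhm_s = 10, scan_rate = 0.94,
                           apex = 1e4, shift_scans = 0) {
  sd_min <- fwhm_s / (2 * sqrt(2 * log(2))) / 60
  dt_min <- 1 / scan_rate / 60
  hw <- sd_min * sqrt(2 * log(4))
  grid <- seq(0, center_min + 10 * hw, by = dt_min)
  ctr <- center_min + shift_scans * dt_min
  keep <- grid >= ctr - hw & grid <= ctr + hw
  data.frame(time = grid[keep],
             intensity = apex * exp(-(grid[keep] - ctr)^2 / (2 * sd_min^2)))
}
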