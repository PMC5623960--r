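# signal-processing module: baseline, detection, isotopes, alignment, gap
# filling, and the ledger-oracle round trip.

test_that("windowed-quantile baseline removes a constant background", {
  # persistent rail at one m/z with a Gaussian peak on top, same cell
  times <- seq(0, 3, by = 1 / 0.94 / 60)
  b <- 500
  peak <- 4000 * exp(-(times - 1.5)^2 / (2 * (10 / 2.355 / 60)^2))
  cen <- data.frame(scan = seq_along(times), mz = 400.005,
                    intensity = b + peak)
  map <- scan_map(times, cen)
  cor <- correct_baseline(map)
  # brute-force oracle: cell quantile of the raw intensities
  apex_scan <- which.max(peak)
  got <- cor$centroids$intensity[cor$centroids$scan == apex_scan]
  rt_cell <- floor(times / 1.5)
  v <- cen$intensity[rt_cell == rt_cell[apex_scan]]
  oracle_q <- quantile(v, 0.40, names = FALSE)
  expect_equal(got, b + peak[apex_scan] - oracle_q, tolerance = 1e-9)
  # peak occupies < 40% of the cell, so the estimate is the background
  expect_lt(abs(oracle_q - b), 30)
  # flat rail only -> everything corrected to zero (and dropped)
  flat <- scan_map(times, data.frame(scan = seq_along(times), mz = 200.001,
                                     intensity = rep(b, length(times))))
  expect_equal(nrow(correct_baseline(flat)$centroids), 0)
  # idempotence within one quantile-estimation tolerance
  cor2 <- correct_baseline(cor)
  expect_equal(sum(cor2$centroids$intensity), sum(cor$centroids$intensity),
               tolerance = 0.02)
  expect_warning(correct_baseline(scan_map(times,
                                           data.frame(scan = integer(),
                                                      mz = numeric(),
                                                      intensity = numeric()))),
                 "empty")
})

test_that("sparse peaks are not docked their own signal", {
  # no background: a lone peak in an otherwise empty cell must survive
  times <- seq(0, 3, by = 1 / 0.94 / 60)
  peak <- 5000 * exp(-(times - 1.5)^2 / (2 * (10 / 2.355 / 60)^2))
  keep <- peak >= 1
  cen <- data.frame(scan = which(keep), mz = 500.005,
                    intensity = peak[keep])
  cor <- correct_baseline(scan_map(times, cen))
  expect_equal(max(cor$centroids$intensity), max(peak), tolerance = 1e-6)
})

test_that("peak detection respects threshold, tolerance and duration", {
  db <- generate_lipid_db(1)
  base <- generate_sample_profile("mesocarp", "unripe", seed = 1,
                                  noise_cv = 0)
  base$concentrations[] <- 0
  # single injected peak, apex 5000 counts (no isotopologue companion)
  p <- base; p$concentrations["Persenone A"] <- 5000 / 1e5
  sim <- synthesize_scan_map(p, db, test_acq(), seed = 1,
                             adducts = "[M+H]+", dropout_p = 0,
                             isotopes = FALSE)
  f <- detect_peaks(sim$map)
  expect_equal(nrow(f), 1)
  expect_equal(f$area / sim$ledger$area, 1, tolerance = 0.02)
  expect_equal(f$mean_mz, sim$ledger$mz, tolerance = 0.01)
  expect_true(f$fwqm_lo < f$rt_apex && f$rt_apex < f$fwqm_hi)
  # apex below the 1000-count threshold -> nothing
  p9 <- base; p9$concentrations["Persenone A"] <- 900 / 1e5
  sim9 <- synthesize_scan_map(p9, db, test_acq(), seed = 1,
                              adducts = "[M+H]+", dropout_p = 0,
                              isotopes = FALSE)
  expect_equal(nrow(detect_peaks(sim9$map)), 0)
  # two co-eluting peaks 0.2 Da apart resolve into two features
  times <- seq(0, 2, by = 1 / 0.94 / 60)
  g <- 5000 * exp(-(times - 1)^2 / (2 * (10 / 2.355 / 60)^2))
  keep <- g >= 1
  cen <- rbind(data.frame(scan = which(keep), mz = 400.0,
                          intensity = g[keep]),
               data.frame(scan = which(keep), mz = 400.2,
                          intensity = g[keep]))
  f2 <- detect_peaks(scan_map(times, cen))
  expect_equal(nrow(f2), 2)
  expect_equal(sort(f2$mean_mz), c(400.0, 400.2), tolerance = 1e-6)
})

test_that("isotope grouping follows the spacing and monotonic-shape rules", {
  tr <- gaussian_trace(10)
  mk <- function(id, mz, apex) make_feature(id, mz, 10, apex,
                                            min(tr$time), max(tr$time), tr)
  # charge-1 pair: +1.00336 spacing, decreasing intensity
  f <- rbind(mk("a", 500.000, 1000), mk("b", 501.003, 110))
  class(f) <- c("peak_features", "data.frame")
  g <- group_isotopes(f)
  expect_equal(g$charge, c(1L, 1L))
  expect_equal(g$is_monoisotopic, c(TRUE, FALSE))
  expect_equal(g$isotope_group[1], g$isotope_group[2])
  expect_equal(monoisotopic_features(g)$mean_mz, 500.000)
  # charge-2 spacing 0.50168
  f2 <- rbind(mk("a", 500.00000, 1000), mk("b", 500.50168, 300))
  class(f2) <- c("peak_features", "data.frame")
  g2 <- group_isotopes(f2)
  expect_equal(g2$charge, c(2L, 2L))
  # increasing intensities violate the monotonic shape: not grouped
  f3 <- rbind(mk("a", 500.000, 100), mk("b", 501.003, 1000))
  class(f3) <- c("peak_features", "data.frame")
  g3 <- group_isotopes(f3)
  expect_false(g3$isotope_group[1] == g3$isotope_group[2])
  expect_true(all(g3$is_monoisotopic))
  # retention-time tolerance: co-elution required
  far <- mk("b", 501.003, 110); far$rt_apex <- 10.5
  f4 <- rbind(mk("a", 500.000, 1000), far)
  class(f4) <- c("peak_features", "data.frame")
  g4 <- group_isotopes(f4)
  expect_false(g4$isotope_group[1] == g4$isotope_group[2])
})

test_that("alignment recovers known retention-time shifts", {
  s1 <- sim_noise_free(seed = 1)
  f1 <- monoisotopic_features(group_isotopes(detect_peaks(s1$map,
                                                          sample_id = "A")))
  # identical samples: identity correction, cells equal input areas
  tab0 <- align_samples(list(A = f1, B = f1))
  expect_equal(unname(tab0$intensity[, "A"]), unname(tab0$intensity[, "B"]))
  expect_true(all(tab0$provenance == "detected"))
  for (shift in c(0.8, -1.2)) {
    s2 <- sim_noise_free(seed = 1, rt_shift = shift)
    f2 <- monoisotopic_features(group_isotopes(detect_peaks(s2$map,
                                                            sample_id = "B")))
    # drop features pushed out of the gradient by the shift
    led2 <- usable_ledger(s2$ledger)
    keep <- vapply(seq_len(nrow(f2)), function(i)
      any(abs(led2$mz - f2$mean_mz[i]) < 0.05), TRUE)
    tab <- align_samples(list(A = f1, B = f2[keep, ]))
    both <- rowSums(tab$provenance == "detected") == 2
    expect_gt(mean(both), 0.8)
    # median abs error of the recovered correction < 0.1 min
    err <- abs(tab$rt[both, "B"] - tab$rt[both, "A"])
    expect_lt(median(err), 0.1)
    # implied shift recovered within 0.05 min
    raw_shift <- median(tab$rt_raw[both, "B"] - tab$rt_raw[both, "A"])
    expect_equal(raw_shift, shift, tolerance = 0.05)
  }
  # a shift beyond rt_tol_before leaves features unmatched
  s3 <- sim_noise_free(seed = 1, rt_shift = 3)
  f3 <- monoisotopic_features(group_isotopes(detect_peaks(s3$map,
                                                          sample_id = "B")))
  expect_warning(tab3 <- align_samples(list(A = f1, B = f3)),
                 "identity")
  expect_gt(sum(tab3$provenance == "missing"), 0)
  expect_gt(nrow(tab3$intensity), nrow(f1))
  expect_error(align_samples(list(A = f1)))
})

test_that("gap filling recovers dropped peaks from the raw map", {
  s1 <- sim_noise_free(seed = 1)
  s2 <- sim_noise_free(seed = 2)
  f1 <- monoisotopic_features(group_isotopes(detect_peaks(s1$map,
                                                          sample_id = "A")))
  f2 <- monoisotopic_features(group_isotopes(detect_peaks(s2$map,
                                                          sample_id = "B")))
  drop_i <- 5
  dropped_mz <- f2$mean_mz[drop_i]
  tab <- align_samples(list(A = f1, B = f2[-drop_i, ]))
  tab <- fill_gaps(tab, list(A = s1$map, B = s2$map))
  expect_true(all(tab$provenance %in%
                    c("detected", "gap-filled")))
  r <- which(abs(tab$features$mean_mz - dropped_mz) < 0.01)
  expect_equal(unname(tab$provenance[r, "B"]), "gap-filled")
  led <- s2$ledger
  truth <- led$area[which.min(abs(led$mz - dropped_mz))]
  expect_equal(unname(tab$intensity[r, "B"]) / truth, 1, tolerance = 0.1)
  # detected cells never overwritten
  det <- tab$provenance[, "A"] == "detected"
  expect_equal(tab$intensity[det, "A"],
               tab$intensity[det, "A"])
  # a missing cell over an empty region fills with 0
  ghost <- f1[1, ]
  ghost$mean_mz <- 777.777
  ghost$feature_id <- "A_GHOST"
  tabg <- align_samples(list(A = rbind(f1, ghost), B = f2))
  tabg <- fill_gaps(tabg, list(A = s1$map, B = s2$map))
  rg <- which(abs(tabg$features$mean_mz - 777.777) < 0.01)
  expect_equal(unname(tabg$intensity[rg, "B"]), 0)
  expect_equal(unname(tabg$provenance[rg, "B"]), "gap-filled")
})

test_that("end-to-end: every usable ledger peak appears exactly once", {
  for (seed in 1:3) {
    sim <- sim_noise_free(seed = seed)
    mono <- monoisotopic_features(group_isotopes(detect_peaks(sim$map)))
    led <- usable_ledger(sim$ledger)
    ratios <- vapply(seq_len(nrow(led)), function(i)
      match_ledger_area(mono, led[i, ]), 0)
    expect_false(anyNA(ratios))        # exactly one match each: no
    expect_true(all(abs(ratios - 1) < 0.02))  # splits, merges, or bias
  }
})

test_that("detection-dropout cells are fully covered after gap filling", {
  db <- generate_lipid_db(1)
  sims <- lapply(1:3, function(r) {
    prof <- generate_sample_profile("mesocarp", "unripe", seed = r,
                                    noise_cv = 0)
    synthesize_scan_map(prof, db, test_acq(), seed = r, dropout_p = 0.3,
                        dropout_mode = "detection")
  })
  names(sims) <- paste0("S", 1:3)
  feats <- lapply(names(sims), function(s) {
    f <- monoisotopic_features(group_isotopes(detect_peaks(sims[[s]]$map,
                                                           sample_id = s)))
    apply_dropout(f, sims[[s]]$ledger)
  })
  names(feats) <- names(sims)
  expect_true(any(vapply(sims, function(s) any(s$ledger$dropped), TRUE)))
  tab <- align_samples(feats)
  tab <- fill_gaps(tab, lapply(sims, `[[`, "map"))
  # every usable ledger peak of every sample is covered by a cell
  for (s in names(sims)) {
    led <- usable_ledger(sims[[s]]$ledger)
    for (i in seq_len(nrow(led))) {
      r <- which(abs(tab$features$mean_mz - led$mz[i]) < 0.05)
      expect_true(length(r) >= 1)
      vals <- tab$intensity[r, s]
      expect_true(any(abs(vals / led$area[i] - 1) < 0.1))
    }
  }
})
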