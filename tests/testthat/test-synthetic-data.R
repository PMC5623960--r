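# synthetic-data module: lipid DB, tissue profiles, growth series, scan
# maps, UV tables.

test_that("formula arithmetic matches the atomic-mass oracle", {
  # frozen from summing IUPAC monoisotopic atomic masses directly
  expect_equal(formula_mass("C27H42O"), 382.3236, tolerance = 1e-3 / 382)
  expect_equal(formula_mass("C25H40O"), 356.3079, tolerance = 1e-3 / 356)
  # independent recomputation, element by element
  oracle <- 23 * 12 + 38 * 1.00782503207 + 4 * 15.9949146196
  expect_equal(formula_mass("C23H38O4"), oracle, tolerance = 1e-10)
  expect_equal(unname(parse_formula("C42H82NO8P")["N"]), 1L)
  expect_error(parse_formula("C2X5"), "unsupported element")
})

test_that("lipid DB honours the worked-example cluster and invariants", {
  for (n in c(12L, 40L, 60L)) {
    db <- generate_lipid_db(seed = 7, n_records = n)
    expect_equal(nrow(db), n)
    cl <- db[db$category == "ST", ]
    expect_equal(as.integer(table(cl$main_class)[c("ST04", "ST03", "ST01")]),
                 c(1L, 3L, 8L))
    expect_equal(cl$formula[cl$main_class == "ST04"], "C25H40O")
    expect_true(all(cl$formula[cl$main_class != "ST04"] == "C27H42O"))
    # mass invariant and class-hierarchy prefix invariant
    expect_true(all(abs(db$monoisotopic_mass -
                          vapply(db$formula, formula_mass, 0)) < 1e-4))
    expect_true(all(startsWith(db$main_class, db$category)))
    expect_true(all(db$subclass == "" |
                      startsWith(db$subclass, db$main_class)))
  }
  db <- generate_lipid_db(1)
  expect_true(all(c("FA", "GL", "GP", "ST") %in% db$category))
  expect_true(all(acetogenin_analytes() %in% db$name))
  expect_error(generate_lipid_db(1, n_records = 11), "12-record")
  # TSV round trip
  path <- tempfile(fileext = ".tsv")
  write_lipid_db(db, path)
  expect_equal(read_lipid_db(path)$monoisotopic_mass, db$monoisotopic_mass)
})

test_that("tissue profiles reproduce the configured means at zero noise", {
  m <- generate_sample_profile("mesocarp", "unripe", seed = 3, noise_cv = 0)
  expect_equal(unname(m$shares["Persenone A"]), 0.527, tolerance = 1e-12)
  expect_equal(unname(m$shares["Persin/Persenone B"]), 0.258,
               tolerance = 1e-12)
  s_young <- generate_sample_profile("seed", "young", seed = 3, noise_cv = 0)
  expect_equal(unname(s_young$shares["AcO-avocadene"]), 0.537,
               tolerance = 1e-12)
  expect_equal(unname(s_young$shares["UPA"]), 0.146, tolerance = 1e-12)
  s_mat <- generate_sample_profile("seed", "mature", seed = 3, noise_cv = 0)
  expect_equal(unname(s_mat$shares["AcO-avocadene"]), 0.363,
               tolerance = 1e-12)
  expect_equal(unname(s_mat$shares["Persin/Persenone B"]), 0.174,
               tolerance = 1e-12)
  # the 4.5-fold TAC regime step, dry-weight basis
  expect_equal(s_mat$tac_dw / s_young$tac_dw, 4.5, tolerance = 1e-9)
  expect_error(generate_sample_profile("mesocarp", "overripe"),
               "unknown stage")
  expect_error(generate_sample_profile("root", "ripe"))
})

test_that("profile invariants hold under noise", {
  for (seed in 1:20) {
    p <- generate_sample_profile(sample(c("mesocarp", "seed"), 1),
                                 sample(tissue_stages()$growth, 1),
                                 seed = seed)
    expect_gt(p$dw_fraction, 0); expect_lt(p$dw_fraction, 1)
    expect_true(all(p$concentrations >= 0))
    expect_equal(sum(p$shares), 1, tolerance = 1e-9)
  }
  # reproducibility: identical seeds give identical samples
  a <- generate_sample_profile("seed", "180g", seed = 11)
  b <- generate_sample_profile("seed", "180g", seed = 11)
  expect_identical(a, b)
})

test_that("idioblast samples are paired to their source mesocarp", {
  m <- generate_sample_profile("mesocarp", "ripe", seed = 9)
  i <- generate_sample_profile("idioblast", "ripe", seed = 9)
  ratio <- i$tac_fw / m$tac_fw
  expect_equal(ratio, i$capture_fraction, tolerance = 1e-12)
  expect_lt(abs(ratio - 0.981), 4 * 0.008)
  # shares identical to the paired mesocarp (fractionation scales uniformly)
  expect_equal(i$shares, m$shares, tolerance = 1e-12)
  i0 <- generate_sample_profile("idioblast", "ripe", seed = 9, noise_cv = 0)
  expect_equal(i0$capture_fraction, 0.981, tolerance = 1e-12)
})

test_that("seed growth series follows TAC = a * DW^b", {
  g <- generate_seed_growth_series(dw_grid = c(1, 2), noise_cv = 0, seed = 1)
  expect_equal(g$tac[1], 32.7, tolerance = 1e-12)
  # 32.7 * 2^2.246, frozen from direct evaluation
  expect_equal(g$tac[2], 155.1176, tolerance = 1e-4 / 155)
  clean <- generate_seed_growth_series(noise_cv = 0, seed = 5)
  fit <- fit_power_law(clean$dry_weight, clean$tac)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(generate_seed_growth_series(dw_grid = c(0.2, -1)), "positive")
  expect_error(generate_seed_growth_series(a = -2), "positive")
})

test_that("scan-map synthesis matches its closed-form ledger", {
  db <- generate_lipid_db(1)
  # degenerate profile: zero concentrations, no noise -> empty map
  p0 <- generate_sample_profile("mesocarp", "unripe", seed = 1, noise_cv = 0)
  p0$concentrations[] <- 0
  s0 <- synthesize_scan_map(p0, db, test_acq(), seed = 1, dropout_p = 0)
  expect_equal(nrow(s0$map$centroids), 0)
  # one analyte, one adduct: integrated trace vs analytic Gaussian area
  p1 <- p0
  p1$concentrations["Persenone A"] <- 0.5
  s1 <- synthesize_scan_map(p1, db, test_acq(), seed = 1,
                            adducts = "[M+H]+", dropout_p = 0,
                            mz_jitter_sd = 0)
  led <- s1$ledger
  expect_equal(nrow(led), 1)
  mono <- s1$map$centroids[abs(s1$map$centroids$mz - led$mz) < 0.01, ]
  tt <- s1$map$scan_times[mono$scan] * 60
  num_area <- sum(diff(tt) * (head(mono$intensity, -1) +
                                tail(mono$intensity, -1)) / 2)
  sigma_s <- led$peak_fwhm_s / (2 * sqrt(2 * log(2)))
  analytic <- led$apex_intensity * sigma_s * sqrt(2 * pi)
  expect_equal(num_area / analytic, 1, tolerance = 0.01)
  expect_equal(led$area, analytic, tolerance = 1e-9)
  # reproducibility: bit-identical maps and ledgers
  s1b <- synthesize_scan_map(p1, db, test_acq(), seed = 1,
                             adducts = "[M+H]+", dropout_p = 0,
                             mz_jitter_sd = 0)
  expect_identical(s1$map$centroids, s1b$map$centroids)
  expect_identical(s1$ledger, s1b$ledger)
  # monotonicity: more analyte never lowers the injected apex
  p2 <- p1; p2$concentrations["Persenone A"] <- 1.0
  s2 <- synthesize_scan_map(p2, db, test_acq(), seed = 1,
                            adducts = "[M+H]+", dropout_p = 0)
  expect_gt(s2$ledger$apex_intensity, s1$ledger$apex_intensity)
  # out-of-range m/z is skipped but logged
  acq_narrow <- acquisition_settings(mz_min = 150, mz_max = 300,
                                     gradient_length = 24, noise_sd = 0,
                                     baseline_amplitude = 0)
  s3 <- synthesize_scan_map(p1, db, acq_narrow, seed = 1,
                            adducts = "[M+H]+", dropout_p = 0)
  expect_true(s3$ledger$skipped_out_of_range)
  expect_equal(nrow(s3$map$centroids), 0)
})

test_that("neutral-lipid region dominates the mesocarp ion current", {
  db <- generate_lipid_db(1)
  prof <- generate_sample_profile("mesocarp", "unripe", seed = 2)
  acq <- acquisition_settings(gradient_length = 65, noise_sd = 0,
                              baseline_amplitude = 0)
  sim <- synthesize_scan_map(prof, db, acq, seed = 2, dropout_p = 0)
  tic <- scan_map_tic(sim$map)
  late <- sum(tic$tic[tic$time >= 40])   # TAG elution region
  early <- sum(tic$tic[tic$time < 40])
  expect_gt(late, early)
})

test_that("UV synthesis is linear and merges the co-eluting pair", {
  curves <- default_calibration_curves()
  p <- generate_sample_profile("mesocarp", "unripe", seed = 1, noise_cv = 0)
  p$concentrations[] <- 0
  a0 <- synthesize_uv_peak_table(p, curves)
  expect_true(all(a0 == 0))
  p$concentrations["Persenone A"] <- 0.6
  a1 <- synthesize_uv_peak_table(p, curves)
  vf <- 15 / 2
  slope <- curves$slope[curves$analyte == "Persenone A"]
  expect_equal(unname(a1["Persenone A"]), slope * 0.6 / vf,
               tolerance = 1e-12)
  # merged co-elution: area proportional to p + q under the B response
  slope_b <- curves$slope[curves$analyte == "Persin/Persenone B"]
  expect_equal(merge_coeluting_areas(0.3, 0.2, slope_b), slope_b * 0.5)
  expect_false("Persin" %in% names(a1))
  expect_true("Persin/Persenone B" %in% names(a1))
})
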