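# End-to-end orchestration.
#
# A pipeline configuration holds the acquisition settings and every stage
# parameter, each defaulting to the published processing values; a run
# executes simulate -> baseline -> detect -> isotopes -> align -> gap-fill
# -> group -> annotate -> quantify -> stats, writes each stage's artifact
# and a manifest with md5 checksums, and is fully deterministic given the
# seeds.

#' Pipeline configuration
#'
#' Stage parameters default to the published processing values (baseline
#' 0.01 Da / 1.5 min / 40% quantile; detection 1000 counts / 0.05 Da /
#' 0.1-2.5 min / 0.1 min smoothing / 0.5 similarity; isotopes 0.001 Da or
#' 10 ppm / 0.25 min / charge <= 2; alignment 0.025 Da or 50 ppm / 2 min /
#' 1.5 min / 25% inliers / 1 min; gap filling 0.025 Da or 50 ppm; grouping
#' correlation > 0.9; annotation window 3 sd + 25 ppm). Overrides are
#' logged with old -> new values when the pipeline runs.
#'
#' @param tissue,stage,replicates Simulated cohort.
#' @param seed Master seed; per-replicate and per-stage seeds derive from it.
#' @param acq [acquisition_settings()]. The default trims the acquisition
#'   to the acetogenin elution window so a full run stays lightweight;
#'   pass the full 65-min window for production-scale simulation.
#' @param dropout_p Feature-dropout probability (0 disables gap filling
#'   exercise).
#' @param n_db_records Size of the fixture lipid database.
#' @param ... Stage parameter overrides, named
#'   `<stage>.<parameter>` (e.g. `detect.min_height = 500`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tissue = "mesocarp", stage = "unripe",
                            replicates = 3L, seed = 1L,
                            acq = acquisition_settings(mz_min = 150,
                                                       mz_max = 900,
                                                       gradient_length = 24,
                                                       noise_sd = 0,
                                                       baseline_amplitude = 0),
                            dropout_p = 0.1,
                            n_db_records = 40L, ...) {
  defaults <- list(
    baseline.mz_window = 0.01, baseline.rt_window = 1.5,
    baseline.quantile = 0.40,
    detect.min_height = 1000, detect.mz_tol = 0.05,
    detect.rt_min = 0.1, detect.rt_max = 2.5,
    detect.smoothing = 0.1, detect.similarity = 0.5,
    isotopes.mz_tol = 0.001, isotopes.ppm = 10, isotopes.rt_tol = 0.25,
    isotopes.max_charge = 2L,
    align.mz_tol = 0.025, align.ppm = 50, align.rt_tol_before = 2,
    align.rt_tol_after = 1.5, align.min_inliers = 0.25,
    align.inlier_threshold = 1,
    gapfill.mz_tol = 0.025, gapfill.ppm = 50,
    group.threshold = 0.9, group.min_scans = 4L,
    annotate.level = 2L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown stage parameter(s): ",
                            paste(unknown, collapse = ", "))
  params <- modifyList(defaults, overrides)
  structure(list(tissue = tissue, stage = stage,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 acq = acq, dropout_p = dropout_p,
                 n_db_records = as.integer(n_db_records),
                 params = params, overrides = overrides),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created if needed).
#' @param verbose Log per-stage counts.
#' @return List of class `pipeline_result`: the lipid DB, per-replicate
#'   profiles / maps / ledgers / features, the gap-filled `feature_table`,
#'   curated groups, annotation candidates and composition profiles,
#'   per-replicate `quant_result`s, the normalized matrix and PCA, and the
#'   manifest path.
#' @export
run_pipeline <- function(config, out_dir = tempfile("persealip_run_"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  p <- config$params
  for (nm in names(config$overrides)) {
    say("config override %s: %s -> %s", nm,
        format(pipeline_config()$params[[nm]]),
        format(config$overrides[[nm]]))
  }

  db <- generate_lipid_db(config$seed, config$n_db_records)
  write_lipid_db(db, file.path(out_dir, "lipid_db.tsv"))

  reps <- seq_len(config$replicates)
  profiles <- maps <- ledgers <- feats <- list()
  for (r in reps) {
    sid <- sprintf("%s_%s_R%d", config$tissue, config$stage, r)
    rseed <- .sub_seed(config$seed, sid)
    prof <- generate_sample_profile(config$tissue, config$stage, rseed)
    sim <- synthesize_scan_map(prof, db, config$acq, seed = rseed,
                               dropout_p = config$dropout_p)
    map <- sim$map
    if (config$acq$baseline_amplitude > 0) {
      map <- correct_baseline(map, p$baseline.mz_window, p$baseline.rt_window,
                              p$baseline.quantile)
    }
    f <- detect_peaks(map, p$detect.min_height, p$detect.mz_tol,
                      p$detect.rt_min, p$detect.rt_max, p$detect.smoothing,
                      p$detect.similarity, sample_id = sid)
    f <- group_isotopes(f, p$isotopes.mz_tol, p$isotopes.ppm,
                        p$isotopes.rt_tol, p$isotopes.max_charge)
    mono <- monoisotopic_features(f)
    # dropout affects detection, not synthesis: remove flagged features
    mono <- apply_dropout(mono, sim$ledger)
    say("%s: %d features (%d monoisotopic after dropout)", sid, nrow(f),
        nrow(mono))
    profiles[[sid]] <- prof; maps[[sid]] <- map
    ledgers[[sid]] <- sim$ledger; feats[[sid]] <- mono
  }

  table <- align_samples(feats, p$align.mz_tol, p$align.ppm,
                         p$align.rt_tol_before, p$align.rt_tol_after,
                         p$align.min_inliers, p$align.inlier_threshold,
                         seed = config$seed)
  table <- fill_gaps(table, maps, p$gapfill.mz_tol, p$gapfill.ppm)
  say("aligned table: %d features, %d gap-filled cells",
      nrow(table$intensity), sum(table$provenance == "gap-filled"))
  write_feature_table(table, file.path(out_dir, "feature_table.csv"))

  first <- feats[[1]]
  groups <- group_by_correlation(first, threshold = p$group.threshold,
                                 min_scans = p$group.min_scans)
  groups <- lapply(groups, curate_group, features = first)
  say("grouping: %d groups from %d features", length(groups), nrow(first))
  write_group_table(groups, file.path(out_dir, "groups.csv"))

  candidates <- do.call(rbind, lapply(seq_len(nrow(first)), function(i) {
    hyp <- enumerate_adducts(first$mean_mz[i], first$charge[i])
    search_db(hyp, db, first$mz_sd[i], feature_id = first$feature_id[i])
  }))
  compositions <- NULL
  if (!is.null(candidates) && nrow(candidates)) {
    compositions <- lapply(split(candidates, candidates$feature_id),
                           classify_composition, level = p$annotate.level)
    write_annotation_report(candidates, file.path(out_dir, "annotation.csv"),
                            compositions)
    say("annotation: %d candidates over %d features", nrow(candidates),
        length(compositions))
  }

  quants <- lapply(names(profiles), function(sid) {
    prof <- profiles[[sid]]
    areas <- synthesize_uv_peak_table(prof, seed = .sub_seed(config$seed, sid))
    quantify(areas, tissue = prof$tissue, dw_fraction = prof$dw_fraction,
             sample_id = sid)
  })
  names(quants) <- names(profiles)

  stats <- NULL
  if (ncol(table$intensity) >= 3 && nrow(table$intensity) >= 2) {
    mat <- table$intensity
    mat[is.na(mat)] <- 0
    keep <- apply(mat, 1, function(v) sd(v) > 0)
    if (sum(keep) >= 2) {
      nm <- normalize_features(mat[keep, , drop = FALSE])
      stats <- list(normalized = nm, pca = run_pca(nm))
    }
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))

  structure(list(config = config, db = db, profiles = profiles, maps = maps,
                 ledgers = ledgers, features = feats, table = table,
                 groups = groups, candidates = candidates,
                 compositions = compositions, quants = quants, stats = stats,
                 out_dir = out_dir,
                 manifest = file.path(out_dir, "manifest.csv")),
            class = "pipeline_result")
}

#' Remove detection-dropout features using the ground-truth ledger
#'
#' Detected features overlapping a ledger peak flagged `dropped` (within
#' 0.05 Da and 0.3 min) are removed, emulating per-sample detection
#' dropout while the raw signal stays available for gap filling.
#'
#' @param features A `peak_features` table.
#' @param ledger The sample's ground-truth ledger.
#' @return The filtered table.
#' @export
apply_dropout <- function(features, ledger) {
  if (!nrow(features) || !nrow(ledger)) return(features)
  drop <- ledger[ledger$dropped & !ledger$skipped_out_of_range, ]
  if (!nrow(drop)) return(features)
  hit <- vapply(seq_len(nrow(features)), function(i) {
    any(abs(drop$mz - features$mean_mz[i]) < 0.05 &
          abs(drop$rt_center - features$rt_apex[i]) < 0.3)
  }, TRUE)
  out <- features[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
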