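# Targeted acetogenin and fatty-acid quantification.
#
# The UV (220 nm) layer: calibration curves per purified analyte, area ->
# concentration inversion with extraction-volume bookkeeping, fresh/dry
# weight conversion, total acetogenin concentration (TAC), profile shares,
# and printed-table style fatty-acid summaries.

# extraction-volume factor: mg/gFW = (mg/mL in injected extract) * factor
# (15 mL acetone over 2 g mesocarp, 1 g seed, 5 g-equivalent idioblasts)
.VOLUME_FACTORS <- c(mesocarp = 15 / 2, seed = 15 / 1, idioblast = 15 / 5)

.DETECTION_LIMIT_FW <- 0.01  # mg/gFW censoring threshold

#' Calibration curve constructor
#'
#' @param analyte Analyte name.
#' @param slope Response slope, area units per (mg/mL); must be positive.
#' @param intercept Area intercept.
#' @param basis Quantification basis: the analyte's own purified standard,
#'   Persenone A equivalents (used for UPA), or the Persenone B curve (used
#'   for the merged, co-eluting Persin/Persenone B peak).
#' @return `data.frame` row of class `calibration_curve`.
#' @export
calibration_curve <- function(analyte, slope, intercept = 0,
                              basis = c("own standard",
                                        "Persenone A equivalents",
                                        "Persenone B curve")) {
  basis <- match.arg(basis)
  if (slope <= 0) stop("calibration slope must be positive")
  out <- data.frame(analyte = analyte, slope = slope, intercept = intercept,
                    basis = basis, stringsAsFactors = FALSE)
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Default calibration-curve set
#'
#' One curve per reported analyte. UPA carries the Persenone A slope
#' (quantified in Persenone A equivalents); the merged Persin/Persenone B
#' peak carries a Persenone B curve. Slopes are synthetic instrument
#' responses shared by the simulator, making quantification the exact
#' inverse of UV synthesis at zero noise.
#'
#' @return `data.frame` with one row per analyte.
#' @export
default_calibration_curves <- function() {
  pa_slope <- 1700
  rbind(
    calibration_curve("AcO-avocadene", 1500),
    calibration_curve("AcO-avocadyne", 1400),
    calibration_curve("AcO-avocadenyne", 1450),
    calibration_curve("UPA", pa_slope, basis = "Persenone A equivalents"),
    calibration_curve("Persenone C", 1600),
    calibration_curve("Persin/Persenone B", 1300, basis = "Persenone B curve"),
    calibration_curve("Persenone A", pa_slope)
  )
}

#' Synthesize a 220-nm UV peak-area table for one sample
#'
#' Forward model of the targeted chromatography: each acetogenin analyte's
#' area is `slope * (mg/mL in the injected extract) * (1 + noise) +
#' intercept`. Persin and Persenone B co-elute and are always emitted as the
#' single merged analyte `"Persin/Persenone B"` under the Persenone B
#' response; [merge_coeluting_areas()] performs that merge when the two
#' concentrations are known separately.
#'
#' @param profile A `tissue_profile`.
#' @param curves Calibration table, as [default_calibration_curves()].
#' @param noise_cv Multiplicative lognormal area noise CV (0 = exact).
#' @param seed Integer seed.
#' @return Named numeric vector of areas, one per analyte in `curves`.
#' @export
synthesize_uv_peak_table <- function(profile, curves = default_calibration_curves(),
                                     noise_cv = 0, seed = 1L) {
  vf <- .VOLUME_FACTORS[[profile$tissue]]
  conc <- profile$concentrations
  eps <- .with_seed(.sub_seed(seed, paste0("uv-", profile$tissue, "-",
                                           profile$stage)),
                    .lnoise(nrow(curves), noise_cv))
  areas <- numeric(nrow(curves))
  names(areas) <- curves$analyte
  for (i in seq_len(nrow(curves))) {
    an <- curves$analyte[i]
    c_fw <- if (an %in% names(conc)) conc[[an]] else 0
    areas[i] <- curves$slope[i] * (c_fw / vf) * eps[i] + curves$intercept[i]
  }
  areas
}

#' Merge co-eluting Persin and Persenone B into one UV area
#'
#' The two analytes cannot be resolved chromatographically; the merged peak
#' responds with the Persenone B slope, so the single area is proportional
#' to the summed concentration under that response.
#'
#' @param persin_conc,persenone_b_conc Concentrations, mg/mL in extract.
#' @param slope_b Persenone B calibration slope.
#' @return Single merged area.
#' @export
merge_coeluting_areas <- function(persin_conc, persenone_b_conc, slope_b) {
  slope_b * (persin_conc + persenone_b_conc)
}

#' Quantify a UV area table against calibration curves
#'
#' Inverts the calibration: `conc_extract = (area - intercept) / slope`,
#' scaled by the tissue's extraction-volume factor to mg per g fresh weight
#' and by the dry-weight fraction to mg per g dry weight. Negative
#' concentrations are clamped to 0 and flagged; values below the 0.01
#' mg/gFW detection limit are flagged censored.
#'
#' @param areas Named numeric vector of 220-nm peak areas.
#' @param curves Calibration table covering every analyte in `areas`.
#' @param tissue Tissue name (selects the extraction-volume factor).
#' @param dw_fraction Dry-weight fraction in (0, 1).
#' @param sample_id Optional identifier.
#' @return `quant_result` list: `conc_fw`, `conc_dw` (named, mg/g), `tac_fw`,
#'   `tac_dw`, `shares` (fractions summing to 1), `flags`.
#' @examples
#' p <- generate_sample_profile("mesocarp", "ripe", seed = 1, noise_cv = 0)
#' a <- synthesize_uv_peak_table(p)
#' q <- quantify(a, tissue = "mesocarp", dw_fraction = p$dw_fraction)
#' round(100 * q$shares["Persenone A"], 1)
#' @export
quantify <- function(areas, curves = default_calibration_curves(),
                     tissue = "mesocarp", dw_fraction = 0.25,
                     sample_id = NA_character_) {
  if (!tissue %in% names(.VOLUME_FACTORS))
    stop("unknown tissue: ", tissue)
  missing_curves <- setdiff(names(areas), curves$analyte)
  if (length(missing_curves))
    stop("no calibration curve for analyte(s): ",
         paste(missing_curves, collapse = ", "))
  vf <- .VOLUME_FACTORS[[tissue]]
  idx <- match(names(areas), curves$analyte)
  conc_ml <- (areas - curves$intercept[idx]) / curves$slope[idx]
  flags <- character(length(areas))
  neg <- conc_ml < 0
  conc_ml[neg] <- 0
  flags[neg] <- "clamped"
  conc_fw <- conc_ml * vf
  low <- !neg & conc_fw > 0 & conc_fw < .DETECTION_LIMIT_FW
  flags[low] <- "below_detection"
  conc_dw <- to_dry_weight(conc_fw, dw_fraction)
  tac_fw <- sum(conc_fw)
  shares <- if (tac_fw > 0) conc_fw / tac_fw else
    setNames(rep(NA_real_, length(conc_fw)), names(conc_fw))
  structure(list(
    sample_id = sample_id, tissue = tissue, dw_fraction = dw_fraction,
    conc_fw = conc_fw, conc_dw = conc_dw,
    tac_fw = tac_fw, tac_dw = tac_fw / dw_fraction,
    shares = shares,
    flags = setNames(flags, names(areas)),
    detection_limit_fw = .DETECTION_LIMIT_FW
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s: TAC %.3f mg/gFW (%.3f mg/gDW)\n",
              x$tissue, x$tac_fw, x$tac_dw))
  invisible(x)
}

#' Convert a fresh-weight concentration to dry-weight basis
#'
#' @param conc_fw Concentration, mg per g fresh weight.
#' @param dw_fraction Dry-weight fraction, strictly inside (0, 1).
#' @return Concentration in mg per g dry weight.
#' @examples
#' to_dry_weight(1, 0.25)  # 4
#' @export
to_dry_weight <- function(conc_fw, dw_fraction) {
  if (any(dw_fraction <= 0) || any(dw_fraction >= 1))
    stop("dw_fraction must lie strictly inside (0, 1)")
  conc_fw / dw_fraction
}

#' Acetogenin profile shares
#'
#' @param quant A `quant_result` with positive TAC.
#' @return Named percentages summing to 100.
#' @export
profile_shares <- function(quant) {
  if (!inherits(quant, "quant_result")) stop("need a quant_result")
  if (!is.finite(quant$tac_fw) || quant$tac_fw <= 0)
    stop("TAC is zero; profile shares undefined")
  100 * quant$conc_fw / quant$tac_fw
}

#' Printed fatty-acid reference values
#'
#' The published per-tissue fatty-acid means and standard deviations
#' (mg/gFW) used as inputs for table arithmetic and as generator targets.
#'
#' @return `data.frame` with `tissue`, `analyte`, `mean`, `sd`.
#' @export
fatty_acid_reference <- function() {
  fa <- c("Linolenic", "Palmitoleic", "Linoleic", "Palmitic", "Oleic",
          "Stearic")
  data.frame(
    tissue = rep(c("mesocarp", "idioblast", "seed"), each = length(fa)),
    analyte = rep(fa, 3),
    mean = c(5.73, 8.12, 14.27, 17.77, 56.30, 6.67,
             0.13, 0.26, 0.69, 0.93, 2.37, 0.21,
             0.22, 0.16, 0.84, 0.90, 0.55, 0.36),
    sd = c(0.03, 0.87, 1.56, 3.49, 8.72, 0.01,
           0.01, 0.08, 0.21, 0.34, 0.80, 0.02,
           0.02, 0.02, 0.13, 0.17, 0.41, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Summarize per-replicate fatty-acid concentrations
#'
#' Computes per-tissue analyte means and standard deviations plus a `Total`
#' column (the sum of the analyte means), the published table layout.
#'
#' @param replicates Long `data.frame` with columns `tissue`, `replicate`,
#'   `analyte`, `conc` (mg/gFW); at least two replicates per tissue.
#' @return List with `means`, `sds` (tissue x analyte matrices, plus a
#'   `Total` column on `means`) and `table` (formatted strings).
#' @export
summarize_fatty_acids <- function(replicates) {
  stopifnot(all(c("tissue", "replicate", "analyte", "conc") %in%
                  names(replicates)))
  nrep <- tapply(replicates$replicate, replicates$tissue,
                 function(x) length(unique(x)))
  if (any(nrep < 2)) stop("need at least two replicates per tissue")
  m <- tapply(replicates$conc, list(replicates$tissue, replicates$analyte),
              mean)
  s <- tapply(replicates$conc, list(replicates$tissue, replicates$analyte),
              sd)
  means <- cbind(m, Total = rowSums(m))
  sds <- s
  table <- matrix(sprintf("%.2f ± %.2f", means,
                          cbind(s, Total = apply(
                            tapply(replicates$conc,
                                   list(replicates$tissue,
                                        replicates$replicate), sum),
                            1, sd))),
                  nrow = nrow(means), dimnames = dimnames(means))
  list(means = means, sds = sds, table = table)
}

#' Cross-tissue fold ratio of analyte means
#'
#' @param means Named numeric vectors (or single numbers): mean
#'   concentration in the numerator and denominator tissue.
#' @param round_to_integer Report as the printed "n-fold" integer.
#' @return Fold ratio(s).
#' @examples
#' fold_ratio(14.27, 0.84)  # 17-fold (linoleic, mesocarp vs seed)
#' @export
fold_ratio <- function(means, denominator, round_to_integer = TRUE) {
  r <- means / denominator
  if (round_to_integer) round(r) else r
}
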