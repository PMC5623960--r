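# Ground-truth tissue lipidomes.
#
# Encodes the study's printed effect structure: mesocarp acetogenin shares
# constant across growth and ripening (Persenone A dominant), seed shares
# shifting between a young (<= 90 g fruit) and a mature (> 90 g) regime with
# a 4.5-fold total-acetogenin (TAC) step, and idioblast fractions paired to
# their source mesocarp sample capturing 98.1% of its acetogenins at the
# ripe stage. Absolute TAC levels and minor-analyte shares are package
# choices (printed figures are images); see the methods vignette.

.ACETOGENINS <- c("AcO-avocadene", "AcO-avocadyne", "AcO-avocadenyne",
                  "UPA", "Persenone C", "Persin/Persenone B", "Persenone A")

.GROWTH_STAGES <- c("45g", "60g", "90g", "120g", "180g", "240g", "300g")
.RIPENING_STAGES <- c("unripe", "breaker", "ripe")

# mean acetogenin shares (sum to 1) per tissue regime
.SHARES <- list(
  mesocarp = c("AcO-avocadene" = 0.120, "AcO-avocadyne" = 0.020,
               "AcO-avocadenyne" = 0.030, "UPA" = 0.025,
               "Persenone C" = 0.020, "Persin/Persenone B" = 0.258,
               "Persenone A" = 0.527),
  seed_young = c("AcO-avocadene" = 0.537, "AcO-avocadyne" = 0.040,
                 "AcO-avocadenyne" = 0.0785, "UPA" = 0.146,
                 "Persenone C" = 0.0334, "Persin/Persenone B" = 0.0451,
                 "Persenone A" = 0.120),
  seed_mature = c("AcO-avocadene" = 0.363, "AcO-avocadyne" = 0.060,
                  "AcO-avocadenyne" = 0.0499, "UPA" = 0.0554,
                  "Persenone C" = 0.0677, "Persin/Persenone B" = 0.174,
                  "Persenone A" = 0.230)
)

# per-analyte replicate CVs derived from the printed share SDs
# (sd / mean of the corresponding pie-chart shares); 0.10 where unprinted
.SHARE_CVS <- list(
  mesocarp = c("AcO-avocadene" = 0.10, "AcO-avocadyne" = 0.10,
               "AcO-avocadenyne" = 0.10, "UPA" = 0.10,
               "Persenone C" = 0.10, "Persin/Persenone B" = 2.3 / 25.8,
               "Persenone A" = 4.3 / 52.7),
  seed_young = c("AcO-avocadene" = 4.43 / 53.7, "AcO-avocadyne" = 0.10,
                 "AcO-avocadenyne" = 1.79 / 7.85, "UPA" = 3.31 / 14.6,
                 "Persenone C" = 0.10, "Persin/Persenone B" = 2.96 / 4.51,
                 "Persenone A" = 0.10),
  seed_mature = c("AcO-avocadene" = 4.88 / 36.3, "AcO-avocadyne" = 0.10,
                  "AcO-avocadenyne" = 3.49 / 4.99, "UPA" = 3.07 / 5.54,
                  "Persenone C" = 0.10, "Persin/Persenone B" = 3.97 / 17.4,
                  "Persenone A" = 0.10)
)

# TAC means, mg per g dry weight
.TAC_DW <- list(mesocarp = 6.0, seed_young = 0.8, seed_mature = 3.6)
.TAC_CV <- list(mesocarp = 0.08, seed = 0.15)

# idioblast capture fraction of mesocarp TAC by stage (98.1 +- 0.8% at ripe)
.IDIO_CAPTURE <- c("unripe" = 0.83, "breaker" = 0.90, "ripe" = 0.981)
.IDIO_CAPTURE_GROWTH <- 0.85
.IDIO_CAPTURE_SD <- 0.008

# bulk glycerolipid pools, mg/gFW, driving the untargeted scan-map structure
.GLYCEROLIPIDS <- function(tissue, stage) {
  ripe_idx <- match(stage, .RIPENING_STAGES)  # NA during growth
  r <- if (is.na(ripe_idx)) 0 else (ripe_idx - 1) / 2
  if (tissue %in% c("mesocarp", "idioblast")) {
    tag <- 100 * (1 - 0.10 * r)        # TAGs decline slightly with ripening
    dag <- 8 * (1 + 0.50 * r)          # DAG remodeling during ripening
  } else {
    young <- stage %in% .GROWTH_STAGES &&
      .stage_weight(stage) <= 90
    tag <- if (young) 30 else 12       # glycerolipid consumption in seed
    dag <- if (young) 5 else 3
  }
  c("TAG 50:1" = 0.25 * tag, "TAG 52:2" = 0.40 * tag, "TAG 54:3" = 0.25 * tag,
    "TAG 54:6" = 0.10 * tag,
    "DAG 34:1" = 0.4 * dag, "DAG 36:2" = 0.4 * dag, "DAG 35:2" = 0.2 * dag,
    "MAG 18:1" = 1.0, "PC 34:1" = 1.2, "PC 36:2" = 0.8, "PE 36:2" = 0.5,
    "Sterol-like 1 (synthetic)" = 0.8)
}

.stage_weight <- function(stage) as.numeric(sub("g$", "", stage))

.canonical_stage <- function(tissue, stage) {
  aliases <- c("young" = "45g", "mature" = "300g", "mature green" = "unripe")
  if (stage %in% names(aliases)) stage <- aliases[[stage]]
  ok <- c(.GROWTH_STAGES, .RIPENING_STAGES)
  if (!stage %in% ok) {
    stop("unknown stage '", stage, "' for tissue '", tissue,
         "'; valid: ", paste(c(ok, names(aliases)), collapse = ", "))
  }
  stage
}

.seed_regime <- function(stage) {
  if (stage %in% .RIPENING_STAGES) return("seed_mature")
  if (.stage_weight(stage) <= 90) "seed_young" else "seed_mature"
}

#' Registry of quantified acetogenin analytes
#'
#' The seven targeted analytes. Persin and Persenone B co-elute in the UV
#' chromatogram and are always reported as the single merged analyte
#' `"Persin/Persenone B"`.
#'
#' @return Character vector of analyte names.
#' @export
acetogenin_analytes <- function() .ACETOGENINS

#' Tissue stages understood by the generator
#' @return Named list with `growth` and `ripening` stage labels.
#' @export
tissue_stages <- function() {
  list(growth = .GROWTH_STAGES, ripening = .RIPENING_STAGES,
       aliases = c(young = "45g", mature = "300g", `mature green` = "unripe"))
}

#' Generate one ground-truth tissue sample
#'
#' Draws a single replicate of the acetogenin and bulk-lipid composition of
#' a tissue at a stage. Replicate noise is multiplicative lognormal, per
#' analyte, with coefficients of variation taken from the printed share
#' standard deviations; a separate lognormal factor models whole-sample TAC
#' variability. `noise_cv = 0` returns the configured means exactly.
#'
#' Idioblast samples are paired to the mesocarp sample that the same seed
#' generates: the idioblast fraction is its source-mesocarp profile scaled
#' by a stage-dependent capture fraction (0.981 at ripe, sd 0.008), so the
#' idioblast/mesocarp TAC ratio is nearly noise-free within a pair, as in a
#' paired fractionation experiment.
#'
#' @param tissue One of `"mesocarp"`, `"idioblast"`, `"seed"`.
#' @param stage Growth stage (`"45g"` ... `"300g"`, alias `"young"`/`"mature"`)
#'   or ripening stage (`"unripe"`, `"breaker"`, `"ripe"`).
#' @param seed Integer seed; equal seeds give the identical (paired) sample.
#' @param noise_cv `NULL` for the per-analyte defaults, or a single
#'   overriding CV (0 disables noise).
#' @return A `tissue_profile` list: `tissue`, `stage`, `fresh_weight` (g),
#'   `dw_fraction`, `concentrations` (named, mg per g fresh weight; includes
#'   bulk glycerolipids), `tac_fw`, `tac_dw`, `shares`.
#' @examples
#' p <- generate_sample_profile("mesocarp", "unripe", seed = 1, noise_cv = 0)
#' round(100 * p$shares["Persenone A"], 1)  # 52.7
#' @export
generate_sample_profile <- function(tissue, stage, seed = 1L,
                                    noise_cv = NULL) {
  tissue <- match.arg(tissue, c("mesocarp", "idioblast", "seed"))
  stage <- .canonical_stage(tissue, stage)
  if (tissue == "seed" && stage %in% .RIPENING_STAGES == FALSE &&
      !stage %in% .GROWTH_STAGES) stop("invalid seed stage")

  if (tissue == "idioblast") {
    meso <- generate_sample_profile("mesocarp", stage, seed, noise_cv)
    capture_mu <- if (stage %in% .RIPENING_STAGES) .IDIO_CAPTURE[[stage]]
                  else .IDIO_CAPTURE_GROWTH
    eps <- if (!is.null(noise_cv) && noise_cv == 0) 0 else
      .with_seed(.sub_seed(seed, paste0("idio-", stage)),
                 rnorm(1, 0, .IDIO_CAPTURE_SD))
    capture <- max(1e-6, capture_mu + eps)
    conc <- meso$concentrations * capture
    out <- meso
    out$tissue <- "idioblast"
    out$concentrations <- conc
    out$capture_fraction <- capture
    aceto <- conc[.ACETOGENINS]
    out$tac_fw <- sum(aceto)
    out$tac_dw <- out$tac_fw / out$dw_fraction
    out$shares <- aceto / sum(aceto)
    return(out)
  }

  regime <- if (tissue == "mesocarp") "mesocarp" else .seed_regime(stage)
  shares <- .SHARES[[regime]]
  cvs <- .SHARE_CVS[[regime]]
  tac_dw_mu <- .TAC_DW[[regime]]
  tac_cv <- if (tissue == "mesocarp") .TAC_CV$mesocarp else .TAC_CV$seed
  if (!is.null(noise_cv)) {
    cvs[] <- noise_cv
    tac_cv <- noise_cv
  }

  growth_i <- match(stage, .GROWTH_STAGES)
  if (tissue == "mesocarp") {
    dw <- if (!is.na(growth_i)) 0.13 + 0.17 * (growth_i - 1) / 6
          else 0.30 + 0.01 * (match(stage, .RIPENING_STAGES) - 1)
    fw <- if (!is.na(growth_i)) .stage_weight(stage) else 250
  } else {
    dw <- if (!is.na(growth_i)) c(0.15, 0.18, 0.22, 0.28, 0.33, 0.38, 0.42)[growth_i]
          else 0.42
    fw <- if (!is.na(growth_i)) .stage_weight(stage) else 250
  }

  draws <- .with_seed(.sub_seed(seed, paste0(tissue, "-", stage)), {
    list(tac = .lnoise(1, tac_cv),
         analyte = .lnoise(length(shares), cvs[names(shares)]))
  })
  conc_dw <- tac_dw_mu * shares * draws$analyte * draws$tac
  conc_fw <- conc_dw * dw

  bulk <- .GLYCEROLIPIDS(tissue, stage)
  bulk_eps <- .with_seed(.sub_seed(seed, paste0(tissue, "-", stage, "-bulk")),
                         .lnoise(length(bulk),
                                 if (is.null(noise_cv)) 0.10 else noise_cv))
  conc <- c(conc_fw, bulk * bulk_eps)

  aceto <- conc[.ACETOGENINS]
  structure(list(
    tissue = tissue, stage = stage, fresh_weight = fw, dw_fraction = dw,
    concentrations = conc,
    tac_fw = sum(aceto), tac_dw = sum(aceto) / dw,
    shares = aceto / sum(aceto)
  ), class = "tissue_profile")
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat("<tissue_profile>", x$tissue, x$stage,
      sprintf("(FW %g g, DW fraction %.2f)\n", x$fresh_weight, x$dw_fraction))
  cat(sprintf("  TAC: %.3f mg/gFW  (%.3f mg/gDW)\n", x$tac_fw, x$tac_dw))
  sh <- sort(x$shares, decreasing = TRUE)
  cat("  shares:", paste(sprintf("%s %.1f%%", names(sh), 100 * sh),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Simulate the seed dry-weight / acetogenin power-law series
#'
#' Generates total-acetogenin concentrations following
#' \eqn{TAC = a \cdot DW^b \cdot \varepsilon} with unit-mean lognormal
#' noise. Defaults encode the printed seed regression
#' (a = 32.7, b = 2.246); `noise_cv = 0.40` reproduces the printed fit
#' quality (R^2 about 0.73) on the default 7-stage x 3-replicate grid.
#'
#' @param dw_grid Seed dry-weight fractions (g DW per g FW), all positive.
#' @param a,b Power-law coefficient and exponent (`a > 0`).
#' @param noise_cv Lognormal coefficient of variation of the multiplicative
#'   noise (0 puts every point exactly on the curve).
#' @param seed Integer seed.
#' @return `data.frame` with `dry_weight` and `tac` (mg per g DW).
#' @examples
#' generate_seed_growth_series(dw_grid = c(1, 2), noise_cv = 0, seed = 1)
#' @export
generate_seed_growth_series <- function(dw_grid = rep(seq(0.13, 0.45,
                                                          length.out = 7),
                                                      each = 3),
                                        a = 32.7, b = 2.246,
                                        noise_cv = 0.40, seed = 1L) {
  if (any(dw_grid <= 0)) stop("dry weights must be positive")
  if (a <= 0) stop("coefficient a must be positive")
  eps <- .with_seed(.sub_seed(seed, "seed-growth"),
                    .lnoise(length(dw_grid), noise_cv))
  data.frame(dry_weight = dw_grid, tac = a * dw_grid^b * eps)
}
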