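# Synthetic ESI-TOF positive-mode acquisition.
#
# A scan map is a time-ordered set of centroid spectra; the simulator
# superposes Gaussian chromatographic peaks (per analyte x adduct, with a
# two-isotopologue envelope), persistent chemical-background "rails" with a
# slow drift, and additive detector noise, and records every injected peak
# in a ground-truth ledger used as the oracle by the processing tests.

.ADDUCT_COMPONENTS <- c(
  "H" = 1.00782503207 - 0.000548579909,
  "NH4" = 14.0030740048 + 4 * 1.00782503207 - 0.000548579909,
  "Na" = 22.9897692809 - 0.000548579909,
  "K" = 38.96370668 - 0.000548579909
)
.SINGLE_ADDUCTS <- c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M+K]+")

# relative electrospray response per adduct in the simulator
.ADDUCT_RESPONSE <- c("[M+H]+" = 1.0, "[M+NH4]+" = 0.25,
                      "[M+Na]+" = 0.40, "[M+K]+" = 0.10)

# Sum of cation-component masses for a label such as "[M+H]+",
# "[M+H+Na]2+" or "[M+2H]2+" (a leading digit multiplies the component).
.adduct_component <- function(label) {
  inner <- sub("^\\[M\\+", "", sub("\\][0-9]?\\+$", "", label))
  parts <- strsplit(inner, "+", fixed = TRUE)[[1]]
  total <- 0
  for (p in parts) {
    mult <- 1L
    if (grepl("^[0-9]", p)) {
      mult <- as.integer(sub("^([0-9]+).*", "\\1", p))
      p <- sub("^[0-9]+", "", p)
    }
    if (!p %in% names(.ADDUCT_COMPONENTS)) stop("unknown adduct part: ", p)
    total <- total + mult * .ADDUCT_COMPONENTS[[p]]
  }
  total
}

.adduct_charge <- function(label) if (grepl("2\\+$", label)) 2L else 1L

#' Acquisition settings
#'
#' Defaults mirror the study's ESI-TOF positive-mode acquisition: m/z
#' 150-1500, 0.94 scans per second, a 65-minute gradient. `noise_sd` is the
#' additive centroid noise (counts) and `baseline_amplitude` the mean
#' intensity of the persistent chemical-background rails.
#'
#' @param mz_min,mz_max Acquisition m/z range, Da.
#' @param scan_rate Scans per second.
#' @param gradient_length Run length, minutes.
#' @param noise_sd Additive noise sd, counts.
#' @param baseline_amplitude Background rail amplitude, counts.
#' @return List of class `acquisition_settings`.
#' @export
acquisition_settings <- function(mz_min = 150, mz_max = 1500,
                                 scan_rate = 0.94, gradient_length = 65,
                                 noise_sd = 30, baseline_amplitude = 200) {
  stopifnot(mz_min < mz_max, scan_rate > 0, gradient_length > 0,
            noise_sd >= 0, baseline_amplitude >= 0)
  structure(list(mz_min = mz_min, mz_max = mz_max, scan_rate = scan_rate,
                 gradient_length = gradient_length, noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude),
            class = "acquisition_settings")
}

#' Construct a scan map from long-format centroids
#'
#' @param scan_times Strictly increasing scan times, minutes.
#' @param centroids `data.frame` with columns `scan` (1-based scan index),
#'   `mz`, `intensity`.
#' @param acq Optional [acquisition_settings()].
#' @return Object of class `scan_map`.
#' @export
scan_map <- function(scan_times, centroids, acq = NULL) {
  stopifnot(all(diff(scan_times) > 0))
  centroids <- data.table::as.data.table(centroids)
  stopifnot(all(c("scan", "mz", "intensity") %in% names(centroids)))
  if (nrow(centroids) && any(centroids$intensity < 0))
    stop("centroid intensities must be non-negative")
  data.table::setorder(centroids, scan, mz)
  structure(list(scan_times = scan_times, centroids = centroids, acq = acq),
            class = "scan_map")
}

#' @export
print.scan_map <- function(x, ...) {
  cat(sprintf("<scan_map> %d scans over %.2f min, %d centroids\n",
              length(x$scan_times),
              diff(range(x$scan_times)), nrow(x$centroids)))
  invisible(x)
}

#' Total ion current of a scan map
#' @param map A `scan_map`.
#' @return `data.frame` with `time` (min) and `tic`.
#' @export
scan_map_tic <- function(map) {
  tic <- rep(0, length(map$scan_times))
  if (nrow(map$centroids)) {
    agg <- tapply(map$centroids$intensity, map$centroids$scan, sum)
    tic[as.integer(names(agg))] <- agg
  }
  data.frame(time = map$scan_times, tic = tic)
}

#' Synthesize an LC-MS scan map from a tissue profile
#'
#' Every analyte in `profile$concentrations` that has a matching record in
#' `db` (by name) and a nonzero concentration is injected as one Gaussian
#' chromatographic peak per configured adduct at the record's nominal
#' retention time, with an M+1 isotopologue at +1.00336/z. All injected
#' peaks are recorded in the ground-truth ledger, including peaks skipped
#' because their m/z falls outside the acquisition range and peaks flagged
#' for dropout.
#'
#' Dropout (Bernoulli per analyte, `dropout_p`) has two modes:
#' `"detection"` (default) keeps the signal in the raw map and only flags
#' the ledger, so gap filling can recover the true area; `"synthesis"`
#' removes the signal entirely.
#'
#' @param profile A [generate_sample_profile()] result.
#' @param db A `lipid_db`.
#' @param acq [acquisition_settings()].
#' @param seed Integer seed.
#' @param adducts Adduct labels to emit per analyte.
#' @param peak_fwhm_s Chromatographic peak full width at half maximum,
#'   seconds. Default 10 s: the width at which the grouping correlation
#'   threshold of 0.9 is equivalent to a one-scan shift (see vignette).
#' @param dropout_p Bernoulli dropout probability per analyte.
#' @param dropout_mode `"detection"` or `"synthesis"`.
#' @param response_factor Apex counts per (mg/gFW) at unit adduct response.
#' @param mz_jitter_sd Per-centroid m/z noise, Da.
#' @param rt_shift Uniform retention-time shift for this sample, minutes
#'   (used to exercise alignment).
#' @param isotopes Emit the M+1 isotopologue peak (default TRUE).
#' @return List with elements `map` (a `scan_map`) and `ledger`
#'   (a `data.frame`, one row per injected adduct peak).
#' @export
synthesize_scan_map <- function(profile, db, acq = acquisition_settings(),
                                seed = 1L,
                                adducts = c("[M+H]+", "[M+Na]+"),
                                peak_fwhm_s = 10, dropout_p = 0.1,
                                dropout_mode = c("detection", "synthesis"),
                                response_factor = 1e5,
                                mz_jitter_sd = 0.002,
                                rt_shift = 0, isotopes = TRUE) {
  stopifnot(inherits(acq, "acquisition_settings"))
  dropout_mode <- match.arg(dropout_mode)
  dt_s <- 1 / acq$scan_rate
  scan_times <- seq(0, acq$gradient_length * 60, by = dt_s) / 60  # minutes
  nscan <- length(scan_times)
  sigma_min <- peak_fwhm_s / (2 * sqrt(2 * log(2))) / 60

  conc <- profile$concentrations
  analytes <- intersect(names(conc), db$name)
  rng <- .rng_stream(seed, "scanmap")

  ledger <- list()
  pieces <- list()
  for (an in analytes) {
    if (conc[[an]] <= 0) next
    rec <- db[match(an, db$name), ]
    env <- isotope_envelope(rec$formula)
    dropped <- rng(1) < dropout_p
    rt0 <- rec$rt_affinity + rt_shift + (rng(1) - 0.5) * 0.05
    for (ad in adducts) {
      z <- .adduct_charge(ad)
      mz0 <- (rec$monoisotopic_mass + .adduct_component(ad)) / z
      apex <- response_factor * conc[[an]] *
        unname(.ADDUCT_RESPONSE[ad] %||% 0.2)
      in_range <- mz0 >= acq$mz_min && mz0 <= acq$mz_max
      truncated <- rt0 < 3 * sigma_min ||
        rt0 > acq$gradient_length - 3 * sigma_min
      area <- apex * sigma_min * 60 * sqrt(2 * pi)  # counts * s
      ledger[[length(ledger) + 1]] <- data.frame(
        analyte = an, adduct = ad, charge = z, mz = mz0,
        rt_center = rt0, peak_fwhm_s = peak_fwhm_s,
        apex_intensity = apex, iso1_rel = unname(env["M1"]),
        area = area, dropped = dropped, skipped_out_of_range = !in_range,
        rt_truncated = truncated,
        stringsAsFactors = FALSE
      )
      if (!in_range) next
      if (dropped && dropout_mode == "synthesis") next
      sel <- which(abs(scan_times - rt0) < 4 * sigma_min)
      if (!length(sel)) next
      shape <- apex * exp(-(scan_times[sel] - rt0)^2 / (2 * sigma_min^2))
      for (iso in 0:(if (isotopes) 1 else 0)) {
        rel <- if (iso == 0) 1 else unname(env["M1"])
        y <- shape * rel
        keep <- y >= 1
        if (!any(keep)) next
        mz_iso <- mz0 + iso * .C13_DELTA / z
        if (mz_iso > acq$mz_max) next
        jit <- if (mz_jitter_sd > 0) rng(sum(keep)) else NULL
        mzv <- rep(mz_iso, sum(keep))
        if (!is.null(jit)) mzv <- mzv + qnorm(jit) * mz_jitter_sd
        pieces[[length(pieces) + 1]] <- data.frame(
          scan = sel[keep], mz = mzv, intensity = y[keep])
      }
    }
  }

  # chemical-background rails with slow drift, plus additive noise
  if (acq$baseline_amplitude > 0) {
    n_rails <- 40L
    rail_mz <- acq$mz_min + (acq$mz_max - acq$mz_min) * rng(n_rails)
    drift <- 0.6 + 0.4 * sin(2 * pi * scan_times /
                               max(scan_times[nscan], 1))
    for (k in seq_len(n_rails)) {
      y <- acq$baseline_amplitude * drift
      if (acq$noise_sd > 0) y <- y + qnorm(rng(nscan)) * acq$noise_sd
      y <- pmax(y, 0)
      pieces[[length(pieces) + 1]] <- data.frame(
        scan = seq_len(nscan), mz = rep(rail_mz[k], nscan), intensity = y)
    }
  } else if (acq$noise_sd > 0 && length(pieces)) {
    # noise on signal centroids only
    for (i in seq_along(pieces)) {
      n <- nrow(pieces[[i]])
      pieces[[i]]$intensity <-
        pmax(pieces[[i]]$intensity + qnorm(rng(n)) * acq$noise_sd, 0)
    }
  }

  centroids <- if (length(pieces)) data.table::rbindlist(pieces)
               else data.table::data.table(scan = integer(), mz = numeric(),
                                           intensity = numeric())
  ledger <- if (length(ledger)) do.call(rbind, ledger)
            else data.frame()
  list(map = scan_map(scan_times, centroids, acq), ledger = ledger)
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
}
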