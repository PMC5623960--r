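# Putative identity assignment.
#
# Observed m/z values are converted to candidate neutral masses under the
# common positive-mode adducts (4 hypotheses for singly charged features,
# 16 ordered pairings for doubly charged — the printed count), searched
# against the local lipid database within a window of 3 standard deviations
# of the m/z measurement plus 25 ppm, verified against the theoretical
# isotope pattern, and summarized as hierarchical class-composition
# profiles ('fixed' when one class holds every surviving candidate,
# 'approximate' otherwise).

#' Enumerate adduct hypotheses for an observed m/z
#'
#' @param mean_mz Observed mean m/z, Da.
#' @param charge 1 or 2.
#' @return `data.frame` with `label`, `charge`, `neutral_mass`, and
#'   `mass_duplicate` (TRUE for the mass-degenerate ordered pairings that
#'   are retained to honor the printed count of 16 but flagged for
#'   reporting-time deduplication).
#' @examples
#' nrow(enumerate_adducts(421.2893, 1))  # 4
#' nrow(enumerate_adducts(421.2893, 2))  # 16
#' @export
enumerate_adducts <- function(mean_mz, charge = 1L) {
  comps <- .ADDUCT_COMPONENTS
  if (charge == 1) {
    labels <- .SINGLE_ADDUCTS
    neutral <- mean_mz - unname(comps)
    out <- data.frame(label = labels, charge = 1L, neutral_mass = neutral,
                      stringsAsFactors = FALSE)
  } else if (charge == 2) {
    grid <- expand.grid(a = names(comps), b = names(comps),
                        stringsAsFactors = FALSE)
    labels <- ifelse(grid$a == grid$b,
                     sprintf("[M+2%s]2+", grid$a),
                     sprintf("[M+%s+%s]2+", grid$a, grid$b))
    neutral <- 2 * mean_mz - comps[grid$a] - comps[grid$b]
    out <- data.frame(label = labels, charge = 2L,
                      neutral_mass = unname(neutral),
                      stringsAsFactors = FALSE)
  } else {
    stop("unsupported charge: ", charge)
  }
  out$mass_duplicate <- duplicated(round(out$neutral_mass, 9))
  out
}

#' Observed m/z implied by a neutral mass and adduct hypothesis
#' @param neutral_mass Neutral monoisotopic mass, Da.
#' @param label Adduct label as produced by [enumerate_adducts()].
#' @return m/z, Da.
#' @export
adduct_mz <- function(neutral_mass, label) {
  (neutral_mass + .adduct_component(label)) / .adduct_charge(label)
}

#' Search the lipid database for adduct hypotheses
#'
#' A record matches a hypothesis when the absolute mass difference does not
#' exceed `3 * mz_sd * charge + 25 ppm` of the neutral mass.
#'
#' @param hypotheses Output of [enumerate_adducts()].
#' @param db A `lipid_db`.
#' @param mz_sd Standard deviation of the feature's m/z measurement, Da.
#' @param feature_id Optional identifier carried into the result.
#' @return Annotation-candidate `data.frame`: `feature_id`, `record_id`,
#'   `name`, `formula`, `adduct`, `category`, `main_class`, `subclass`,
#'   `mass_error_ppm`, `isotope_check` (initialized `"untested"`).
#' @export
search_db <- function(hypotheses, db, mz_sd, feature_id = NA_character_) {
  if (!nrow(db)) {
    warning("empty lipid database; no candidates")
    return(data.frame())
  }
  out <- list()
  for (k in seq_len(nrow(hypotheses))) {
    nm <- hypotheses$neutral_mass[k]
    window <- 3 * mz_sd * hypotheses$charge[k] + 25e-6 * nm
    hit <- which(abs(db$monoisotopic_mass - nm) <= window)
    if (!length(hit)) next
    out[[length(out) + 1]] <- data.frame(
      feature_id = feature_id,
      record_id = db$record_id[hit], name = db$name[hit],
      formula = db$formula[hit], adduct = hypotheses$label[k],
      category = db$category[hit], main_class = db$main_class[hit],
      subclass = db$subclass[hit],
      mass_error_ppm = 1e6 * (db$monoisotopic_mass[hit] - nm) / nm,
      isotope_check = "untested",
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(feature_id = character(), record_id = character(),
                      name = character(), formula = character(),
                      adduct = character(), category = character(),
                      main_class = character(), subclass = character(),
                      mass_error_ppm = numeric(),
                      isotope_check = character()))
  }
  do.call(rbind, out)
}

.adduct_atoms <- function(label) {
  # atom counts added by the adduct (for isotope-pattern computation)
  inner <- sub("^\\[M\\+", "", sub("\\][0-9]?\\+$", "", label))
  if (grepl("^2", inner)) inner <- paste(sub("^2", "", inner),
                                         sub("^2", "", inner), sep = "+")
  parts <- strsplit(inner, "+", fixed = TRUE)[[1]]
  atoms <- c(C = 0L, H = 0L, N = 0L)
  for (p in parts) {
    if (p == "H") atoms["H"] <- atoms["H"] + 1L
    else if (p == "NH4") { atoms["N"] <- atoms["N"] + 1L
                           atoms["H"] <- atoms["H"] + 4L }
    # Na / K add no C, H or N and do not alter the light-isotope envelope
  }
  atoms[atoms > 0]
}

#' Verify a candidate's isotopic pattern
#'
#' The theoretical envelope is computed from the candidate formula plus
#' adduct atoms; the candidate passes when every theoretical isotopologue
#' relative intensity lies within the observed value plus or minus
#' `sd / r^2 + 0.05 * intensity`, where `r` is the correlation of the
#' isotopologue trace to the monoisotopic trace. `r = 0` makes the window
#' infinite; such candidates are flagged degenerate and failed.
#'
#' @param formula Candidate molecular formula (neutral molecule).
#' @param adduct Adduct label (its atoms join the envelope computation).
#' @param observed `data.frame` with one row per isotopologue beyond the
#'   monoisotopic peak (M+1, optionally M+2): columns `rel_intensity`
#'   (relative to the monoisotopic intensity), `sd`, `r`.
#' @return List: `pass` (logical), `degenerate`, `details` per isotopologue.
#' @export
verify_isotopes <- function(formula, adduct = "[M+H]+", observed) {
  stopifnot(all(c("rel_intensity", "sd", "r") %in% names(observed)))
  counts <- parse_formula(formula)
  extra <- .adduct_atoms(adduct)
  for (el in names(extra)) {
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + extra[[el]]
  }
  theo <- isotope_envelope(counts)[-1]  # M+1, M+2
  n <- min(nrow(observed), length(theo))
  if (any(observed$r[seq_len(n)] == 0)) {
    return(list(pass = FALSE, degenerate = TRUE, details = NULL))
  }
  details <- data.frame(
    isotopologue = paste0("M+", seq_len(n)),
    theoretical = theo[seq_len(n)],
    observed = observed$rel_intensity[seq_len(n)],
    window = observed$sd[seq_len(n)] / observed$r[seq_len(n)]^2 +
      0.05 * observed$rel_intensity[seq_len(n)]
  )
  details$ok <- abs(details$theoretical - details$observed) <= details$window
  list(pass = all(details$ok), degenerate = FALSE, details = details)
}

#' Hierarchical class composition of a candidate set
#'
#' Weight of class c at the requested level = (candidates in c) / (total
#' candidates). The profile is 'fixed' when a single class holds weight 1.
#'
#' @param candidates Candidate `data.frame` (from [search_db()] or
#'   [worked_example_candidates()]); rows with `isotope_check == "fail"`
#'   are excluded.
#' @param level 1 (category), 2 (main class) or 3 (subclass).
#' @return List of class `composition_profile`: `level`, `weights` (named,
#'   summing to 1), `fixed`, `n_candidates`.
#' @examples
#' cc <- worked_example_candidates()
#' classify_composition(cc, level = 2)$weights  # 8.3% / 25% / 66.7%
#' @export
classify_composition <- function(candidates, level = 2L) {
  stopifnot(level %in% 1:3)
  if (!nrow(candidates)) {
    return(structure(list(level = level, weights = numeric(0), fixed = NA,
                          n_candidates = 0L, unannotated = TRUE),
                     class = "composition_profile"))
  }
  keep <- candidates$isotope_check != "fail"
  cc <- candidates[keep, , drop = FALSE]
  col <- c("category", "main_class", "subclass")[level]
  tab <- table(cc[[col]])
  weights <- as.numeric(tab) / sum(tab)
  names(weights) <- names(tab)
  weights <- sort(weights, decreasing = TRUE)
  structure(list(level = level, weights = weights,
                 fixed = length(weights) == 1L,
                 n_candidates = nrow(cc), unannotated = FALSE),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  tag <- if (isTRUE(x$fixed)) "fixed" else "approximate"
  cat(sprintf("<composition_profile> level %d (%s): %s\n", x$level, tag,
              paste(sprintf("%s %.1f%%", names(x$weights), 100 * x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Flag putative-acetogenin signature groups
#'
#' A feature group is flagged putative-acetogenin when (a) at least one
#' surviving candidate formula has four or more oxygens and an odd carbon
#' count, and (b) the group contains an acetoxy-loss fragment pair
#' (mass difference 60.0211 Da).
#'
#' @param group A curated group (see [curate_group()]).
#' @param candidates Candidate table for the group's features.
#' @return List: `flagged`, `formula_criterion`, `fragment_criterion`.
#' @export
flag_acetogenin_signatures <- function(group, candidates) {
  formula_ok <- FALSE
  if (nrow(candidates)) {
    for (f in unique(candidates$formula[candidates$isotope_check != "fail"])) {
      counts <- parse_formula(f)
      nC <- if ("C" %in% names(counts)) counts[["C"]] else 0L
      nO <- if ("O" %in% names(counts)) counts[["O"]] else 0L
      if (nO >= 4 && nC %% 2 == 1) { formula_ok <- TRUE; break }
    }
  }
  fragment_ok <- isTRUE(group$acetoxy_loss_pair)
  list(flagged = formula_ok && fragment_ok,
       formula_criterion = formula_ok,
       fragment_criterion = fragment_ok)
}
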