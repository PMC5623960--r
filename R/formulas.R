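#' @importFrom stats aov approx cor dist hclust lm loess lowess median nls
#'   predict prcomp ptukey quantile rbinom rlnorm rnorm runif sd setNames
#'   t.test TukeyHSD var as.dist coef resid qtukey complete.cases
#' @importFrom utils head tail modifyList
NULL

# Monoisotopic atomic masses (IUPAC 2021), Da.
.ELEMENT_MASSES <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.9897692809,
  K = 38.96370668
)

.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS <- 1.00782503207 - .ELECTRON_MASS
# C13 - C12 mass difference; isotopologue spacing per unit charge.
.C13_DELTA <- 1.0033548378

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula such as `"C27H42O"` into a named integer
#' vector of element counts.
#'
#' @param formula Character scalar, e.g. `"C23H38O4"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C27H42O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  els <- sub("[0-9]+$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  unknown <- setdiff(els, names(.ELEMENT_MASSES))
  if (length(unknown)) stop("unsupported element(s): ",
                            paste(unknown, collapse = ", "))
  counts <- tapply(cnt, els, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of a formula
#'
#' @param formula Formula string or named count vector from [parse_formula()].
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("C27H42O")  # 382.3236
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.ELEMENT_MASSES[names(counts)] * counts)
}

#' Approximate isotopologue envelope of a formula
#'
#' Two-isotopologue-plus approximation used both by the simulator and by
#' isotope-pattern verification: the M+1 relative abundance is driven by the
#' carbon count (1.1% per carbon, plus minor H/N terms), M+2 by the paired
#' C13 term and O18. Truncated at M+2; heavier isotopologues are below the
#' simulated noise floor in the 150-1500 Da range.
#'
#' @param formula Formula string or count vector (include adduct atoms when
#'   verifying an observed ion).
#' @return Numeric vector of relative abundances `c(M = 1, M1, M2)`.
#' @export
isotope_envelope <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  n <- function(el) if (el %in% names(counts)) counts[[el]] else 0L
  p1 <- 0.011 * n("C") + 0.000115 * n("H") + 0.00364 * n("N")
  p2 <- (0.011 * n("C"))^2 / 2 + 0.00205 * n("O")
  c(M = 1, M1 = unname(p1), M2 = unname(p2))
}
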