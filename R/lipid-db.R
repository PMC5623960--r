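# Fixture lipid reference database.
#
# Stands in for a remote structure-database lookup: a local table of
# synthetic-but-plausible records with a three-level class hierarchy
# (category / main class / subclass). The mandatory 12-record sterol cluster
# (one ST04, three ST03 with formula C27H42O typo'd in print as C25H40O for
# the ST04 member, eight ST01) reproduces the worked annotation example's
# class counts.

# Core fixture entries: quantified acetogenins (FA category), glycerolipids,
# glycerophospholipids, and the sterol worked-example cluster.
.db_core <- function() {
  rec <- function(id, name, formula, cat, main, sub, rt) {
    list(record_id = id, name = name, formula = formula,
         category = cat, main_class = main, subclass = sub, rt_affinity = rt)
  }
  aceto <- list(
    rec("PLP0001", "AcO-avocadene",      "C19H36O4", "FA", "FA12", "FA1201", 9.0),
    rec("PLP0002", "AcO-avocadyne",      "C19H32O4", "FA", "FA12", "FA1201", 10.5),
    rec("PLP0003", "AcO-avocadenyne",    "C19H34O4", "FA", "FA12", "FA1201", 12.0),
    rec("PLP0004", "UPA",                "C23H38O5", "FA", "FA12", "FA1202", 13.5),
    rec("PLP0005", "Persenone C",        "C23H36O4", "FA", "FA12", "FA1203", 15.0),
    rec("PLP0006", "Persin/Persenone B", "C23H40O4", "FA", "FA12", "FA1203", 16.5),
    rec("PLP0007", "Persenone A",        "C23H38O4", "FA", "FA12", "FA1203", 18.0)
  )
  fa <- list(
    rec("PLP0010", "Palmitic acid",  "C16H32O2", "FA", "FA01", "FA0101", 8.0),
    rec("PLP0011", "Oleic acid",     "C18H34O2", "FA", "FA01", "FA0103", 9.5),
    rec("PLP0012", "Linoleic acid",  "C18H32O2", "FA", "FA01", "FA0103", 8.6),
    rec("PLP0013", "Linolenic acid", "C18H30O2", "FA", "FA01", "FA0103", 8.2)
  )
  gl <- list(
    rec("PLP0020", "MAG 18:1",  "C21H40O4",  "GL", "GL01", "GL0101", 22.0),
    rec("PLP0021", "DAG 34:1",  "C37H70O5",  "GL", "GL02", "GL0201", 27.0),
    rec("PLP0022", "DAG 36:2",  "C39H72O5",  "GL", "GL02", "GL0201", 31.0),
    rec("PLP0023", "DAG 35:2",  "C38H70O5",  "GL", "GL02", "GL0201", 35.0),
    rec("PLP0024", "TAG 50:1",  "C53H100O6", "GL", "GL03", "GL0301", 47.0),
    rec("PLP0025", "TAG 52:2",  "C55H102O6", "GL", "GL03", "GL0301", 51.0),
    rec("PLP0026", "TAG 54:3",  "C57H104O6", "GL", "GL03", "GL0301", 55.0),
    rec("PLP0027", "TAG 54:6",  "C57H98O6",  "GL", "GL03", "GL0301", 58.0)
  )
  gp <- list(
    rec("PLP0030", "PC 34:1", "C42H82NO8P", "GP", "GP01", "GP0101", 24.0),
    rec("PLP0031", "PC 36:2", "C44H84NO8P", "GP", "GP01", "GP0101", 26.0),
    rec("PLP0032", "PE 36:2", "C41H78NO8P", "GP", "GP02", "GP0201", 23.0)
  )
  # Worked-example sterol cluster: printed class counts {ST04:1, ST03:3,
  # ST01:8}. The single ST04 member keeps the printed formula C25H40O even
  # though that formula is inconsistent with the printed m/z (see vignette).
  st <- c(
    list(rec("PLP0040", "Bile acid derivative (synthetic stand-in)",
             "C25H40O", "ST", "ST04", "ST0401", 20.0)),
    lapply(1:3, function(i)
      rec(sprintf("PLP004%d", i), sprintf("Secosteroid-like %d (synthetic)", i),
          "C27H42O", "ST", "ST03", "ST0301", 20.0 + 0.2 * i)),
    lapply(1:8, function(i)
      rec(sprintf("PLP005%d", i - 1), sprintf("Sterol-like %d (synthetic)", i),
          "C27H42O", "ST", "ST01", "ST0101", 21.0 + 0.2 * i))
  )
  c(aceto, fa, gl, gp, st)
}

#' Generate the fixture lipid reference database
#'
#' Builds a reproducible local lipid table spanning the FA (including the
#' seven quantified aliphatic acetogenins), GL (MAG/DAG/TAG), GP and ST
#' categories. Always contains the 12-record sterol worked-example cluster
#' with class counts ST04:1, ST03:3, ST01:8. Records beyond the core set are
#' filler TAG/DAG homologues with seeded retention-time jitter.
#'
#' @param seed Integer seed controlling filler-record jitter.
#' @param n_records Total number of records requested (>= 12).
#' @return A `data.frame` of class `lipid_db` with columns `record_id`,
#'   `name`, `formula`, `monoisotopic_mass`, `category`, `main_class`,
#'   `subclass`, `rt_affinity`.
#' @examples
#' db <- generate_lipid_db(seed = 1)
#' subset(db, main_class == "ST01")
#' @export
generate_lipid_db <- function(seed = 1L, n_records = 40L) {
  if (n_records < 12L) {
    stop("n_records = ", n_records, " cannot house the mandatory ",
         "12-record worked-example sterol cluster (need >= 12)")
  }
  core <- .db_core()
  rng <- .rng_stream(seed, "lipid_db")
  recs <- core
  if (n_records > length(core)) {
    extra <- n_records - length(core)
    # filler: TAG/DAG homologue series
    fills <- lapply(seq_len(extra), function(i) {
      nc <- 49 + 2 * (i %% 6)
      dag <- i %% 2 == 0
      list(record_id = sprintf("PLPF%03d", i),
           name = sprintf("%s homologue %d (synthetic)",
                          if (dag) "DAG" else "TAG", i),
           formula = if (dag) sprintf("C%dH%dO5", nc - 12, 2 * (nc - 12) - 2)
                     else sprintf("C%dH%dO6", nc, 2 * nc - 6),
           category = "GL", main_class = if (dag) "GL02" else "GL03",
           subclass = if (dag) "GL0201" else "GL0301",
           rt_affinity = if (dag) 25 + 15 * rng() else 45 + 15 * rng())
    })
    recs <- c(recs, fills)
  } else if (n_records < length(core)) {
    # keep the sterol cluster (last 12) plus the first records
    keep_head <- n_records - 12L
    recs <- c(core[seq_len(keep_head)], core[seq(length(core) - 11L, length(core))])
  }
  db <- data.frame(
    record_id = vapply(recs, `[[`, "", "record_id"),
    name = vapply(recs, `[[`, "", "name"),
    formula = vapply(recs, `[[`, "", "formula"),
    monoisotopic_mass = vapply(recs, function(r) formula_mass(r$formula), 0),
    category = vapply(recs, `[[`, "", "category"),
    main_class = vapply(recs, `[[`, "", "main_class"),
    subclass = vapply(recs, `[[`, "", "subclass"),
    rt_affinity = vapply(recs, `[[`, 0, "rt_affinity"),
    stringsAsFactors = FALSE
  )
  stopifnot(all(startsWith(db$main_class, db$category)))
  class(db) <- c("lipid_db", "data.frame")
  db
}

#' Worked-example annotation candidate set
#'
#' Assembles the 12 sterol-cluster records of the fixture database into an
#' annotation-candidate table (class counts ST04:1, ST03:3, ST01:8), the
#' input of the printed class-composition example. The printed example
#' attaches these candidates to the feature at mean m/z 421.2893 via the
#' adducts \eqn{[M+H]^+} and \eqn{[M+K]^+}; the first formula is
#' typographically inconsistent with that m/z, so a faithful mass search
#' returns 11 of the 12 (see the methods vignette) and this constructor
#' provides the printed set directly.
#'
#' @param db A `lipid_db`; defaults to `generate_lipid_db()`.
#' @return Annotation candidate `data.frame` (see [search_db()]).
#' @export
worked_example_candidates <- function(db = generate_lipid_db()) {
  idx <- db$formula %in% c("C25H40O", "C27H42O") &
    db$category == "ST"
  recs <- db[idx, , drop = FALSE]
  data.frame(
    feature_id = "F421.3-12.0",
    record_id = recs$record_id,
    name = recs$name,
    formula = recs$formula,
    adduct = ifelse(recs$formula == "C25H40O", "[M+H]+", "[M+K]+"),
    category = recs$category,
    main_class = recs$main_class,
    subclass = recs$subclass,
    mass_error_ppm = 0,
    isotope_check = "pass",
    stringsAsFactors = FALSE
  )
}

#' Write / read the lipid database as TSV
#'
#' Plain UTF-8 TSV with header `record_id, name, formula, mass, category,
#' main_class, subclass` (plus `rt_affinity`); round-trips exactly.
#'
#' @param db A `lipid_db` data frame.
#' @param path File path.
#' @return `read_lipid_db` returns the `lipid_db` data frame.
#' @export
write_lipid_db <- function(db, path) {
  out <- db
  names(out)[names(out) == "monoisotopic_mass"] <- "mass"
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_lipid_db
#' @export
read_lipid_db <- function(path) {
  db <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("record_id", "name", "formula", "mass", "category",
            "main_class", "subclass")
  miss <- setdiff(need, names(db))
  if (length(miss)) stop("lipid DB missing column(s): ",
                         paste(miss, collapse = ", "))
  names(db)[names(db) == "mass"] <- "monoisotopic_mass"
  class(db) <- c("lipid_db", "data.frame")
  db
}
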