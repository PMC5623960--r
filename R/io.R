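# Readers and writers.
#
# The pipeline standardizes on two scan-map formats: a documented
# long-format CSV (scan_time_min, mz, intensity; UTF-8, header row, '.'
# decimal) and a minimal mzML 1.1 document (64-bit little-endian,
# uncompressed, base64 binary arrays, MS1 centroid spectra). MS2 spectra in
# input mzML are ignored with a warning. Feature tables, ledgers and
# profiles round-trip through plain CSV.

#' Write a scan map
#'
#' @param map A `scan_map`.
#' @param path Output path; format chosen by extension (`.csv` or `.mzML`)
#'   unless `format` is given.
#' @param format `"csv"` or `"mzml"`.
#' @return The path, invisibly.
#' @export
write_scan_map <- function(map, path, format = NULL) {
  format <- format %||% (if (grepl("\\.mzml$", path, ignore.case = TRUE))
                           "mzml" else "csv")
  if (format == "csv") {
    df <- data.frame(scan_time_min = map$scan_times[map$centroids$scan],
                     mz = map$centroids$mz,
                     intensity = map$centroids$intensity)
    data.table::fwrite(df, path)
  } else {
    .write_mzml(map, path)
  }
  invisible(path)
}

#' Read a scan map
#'
#' @param path `.csv` (long format) or `.mzML` file.
#' @param scan_times Optional full scan-time grid (minutes) for CSV input;
#'   when absent, the distinct observed times are used.
#' @return A `scan_map`.
#' @export
read_scan_map <- function(path, scan_times = NULL) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) return(.read_mzml(path))
  df <- as.data.frame(data.table::fread(path))
  need <- c("scan_time_min", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("scan-map CSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  times <- scan_times %||% sort(unique(df$scan_time_min))
  # snap to the nearest grid time (text round-trips truncate precision)
  mid <- (times[-1] + times[-length(times)]) / 2
  scan <- findInterval(df$scan_time_min, mid) + 1L
  if (any(abs(times[scan] - df$scan_time_min) > 1e-6))
    stop("scan-map CSV ", path, ": times not on the provided scan grid")
  scan_map(times, data.frame(scan = scan, mz = df$mz,
                             intensity = df$intensity))
}

.b64_doubles <- function(x) jsonlite::base64_enc(writeBin(as.double(x),
                                                          raw(),
                                                          size = 8,
                                                          endian = "little"))

.unb64_doubles <- function(s) readBin(jsonlite::base64_dec(s), "double",
                                      n = 1e7, size = 8, endian = "little")

.write_mzml <- function(map, path) {
  scans <- split(seq_len(nrow(map$centroids)), map$centroids$scan)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <run id="run1">')
  w(sprintf('    <spectrumList count="%d">', length(map$scan_times)))
  for (si in seq_along(map$scan_times)) {
    idx <- scans[[as.character(si)]]
    mz <- if (is.null(idx)) numeric() else map$centroids$mz[idx]
    it <- if (is.null(idx)) numeric() else map$centroids$intensity[idx]
    w(sprintf('      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              si - 1L, si, length(mz)))
    w('        <cvParam accession="MS:1000511" name="ms level" value="1"/>')
    w(sprintf('        <cvParam accession="MS:1000016" name="scan start time" value="%.8f" unitName="minute"/>',
              map$scan_times[si]))
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray><cvParam accession="MS:1000514" name="m/z array"/><binary>',
      .b64_doubles(mz), '</binary></binaryDataArray>')
    w('          <binaryDataArray><cvParam accession="MS:1000515" name="intensity array"/><binary>',
      .b64_doubles(it), '</binary></binaryDataArray>')
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}

.read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  spectra <- xml2::xml_find_all(doc, ".//m:spectrum", ns)
  if (!length(spectra)) stop("mzML file ", path, " contains no spectra")
  times <- numeric()
  pieces <- list()
  skipped_ms2 <- 0L
  si <- 0L
  for (sp in spectra) {
    lvl <- xml2::xml_attr(
      xml2::xml_find_first(sp, ".//m:cvParam[@accession='MS:1000511']", ns),
      "value")
    if (!is.na(lvl) && lvl != "1") { skipped_ms2 <- skipped_ms2 + 1L; next }
    tt <- as.numeric(xml2::xml_attr(
      xml2::xml_find_first(sp, ".//m:cvParam[@accession='MS:1000016']", ns),
      "value"))
    arrays <- xml2::xml_find_all(sp, ".//m:binaryDataArray", ns)
    get_arr <- function(acc) {
      for (a in arrays) {
        if (!is.na(xml2::xml_attr(
          xml2::xml_find_first(a, sprintf(".//m:cvParam[@accession='%s']",
                                          acc), ns), "name"))) {
          b <- xml2::xml_text(xml2::xml_find_first(a, ".//m:binary", ns))
          return(if (nzchar(trimws(b))) .unb64_doubles(trimws(b))
                 else numeric())
        }
      }
      numeric()
    }
    mz <- get_arr("MS:1000514")
    it <- get_arr("MS:1000515")
    si <- si + 1L
    times[si] <- tt
    if (length(mz))
      pieces[[length(pieces) + 1]] <- data.frame(scan = si, mz = mz,
                                                 intensity = it)
  }
  if (skipped_ms2)
    warning(skipped_ms2, " MS2 spectra ignored (only MS1 is in scope)")
  centroids <- if (length(pieces)) do.call(rbind, pieces)
               else data.frame(scan = integer(), mz = numeric(),
                               intensity = numeric())
  scan_map(times, centroids)
}

#' Write / read an aligned feature table as CSV
#'
#' Layout: `feature_id`, `mean_mz`, `rt`, then one intensity and one
#' provenance column per sample.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `read_feature_table` rebuilds the `feature_table` (without the
#'   per-sample retention-time matrices).
#' @export
write_feature_table <- function(table, path) {
  df <- table$features[, c("feature_id", "mean_mz", "rt")]
  for (s in colnames(table$intensity)) {
    df[[paste0("intensity_", s)]] <- table$intensity[, s]
    df[[paste0("provenance_", s)]] <- table$provenance[, s]
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("feature_id", "mean_mz", "rt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature-table CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  icols <- grep("^intensity_", names(df), value = TRUE)
  samples <- sub("^intensity_", "", icols)
  intensity <- as.matrix(df[icols])
  colnames(intensity) <- samples
  provenance <- as.matrix(df[paste0("provenance_", samples)])
  colnames(provenance) <- samples
  structure(list(features = df[need], intensity = intensity,
                 provenance = provenance, rt = NULL, rt_raw = NULL,
                 corrections = NULL),
            class = "feature_table")
}

#' Write an annotation report as CSV
#'
#' @param candidates Candidate table (see [search_db()]).
#' @param compositions Optional named list of `composition_profile`s per
#'   feature, appended as weight strings.
#' @param path CSV path.
#' @export
write_annotation_report <- function(candidates, path, compositions = NULL) {
  df <- candidates
  if (!is.null(compositions)) {
    df$composition <- vapply(df$feature_id, function(f) {
      cp <- compositions[[f]]
      if (is.null(cp)) return("")
      paste(sprintf("%s:%.3f", names(cp$weights), cp$weights),
            collapse = ";")
    }, "")
  }
  data.table::fwrite(df, path)
  invisible(path)
}
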