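# Co-elution grouping by trace correlation.
#
# Within one sample, features whose FWQM retention windows overlap are
# candidates to originate from the same molecule (adducts, fragments,
# detector artifacts); candidacy is confirmed when the Pearson correlation
# of their per-scan intensity traces over the common scans exceeds 0.9
# (strictly). Admitted pairs are merged by single-linkage closure. The 0.9
# threshold rejects even an identically shaped peak shifted by one scan at
# the default peak width (see vignette).

#' Candidate co-elution pairs
#'
#' @param features A `peak_features` table with FWQM bounds populated.
#' @return `data.frame` of candidate index pairs `(i, j)`, `i < j`, whose
#'   closed FWQM intervals intersect.
#' @export
find_candidates <- function(features) {
  n <- nrow(features)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      js <- which(features$fwqm_lo[(i + 1):n] <= features$fwqm_hi[i] &
                    features$fwqm_hi[(i + 1):n] >= features$fwqm_lo[i]) + i
      if (length(js)) out[[length(out) + 1]] <- data.frame(i = i, j = js)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  do.call(rbind, out)
}

.trace_correlation <- function(tr_i, tr_j, min_scans = 4L) {
  key_i <- round(tr_i$time * 1e6)
  key_j <- round(tr_j$time * 1e6)
  common <- intersect(key_i, key_j)
  if (length(common) < min_scans) return(NA_real_)
  xi <- tr_i$intensity[match(common, key_i)]
  xj <- tr_j$intensity[match(common, key_j)]
  if (sd(xi) == 0 || sd(xj) == 0) return(NA_real_)
  cor(xi, xj)
}

#' Group candidate pairs by trace correlation
#'
#' @param features A `peak_features` table (one sample).
#' @param candidates Pairs from [find_candidates()]; computed when `NULL`.
#' @param threshold Correlation threshold; admission is strict (`> 0.9`).
#' @param min_scans Minimum number of common scans for a valid correlation
#'   (pairs with fewer are rejected and logged in the result).
#' @return List of class `feature_groups`: per group `members` (row
#'   indices), `feature_ids`, `representative` (highest summed trace
#'   intensity), `consensus_rt`, `correlations` (matrix); plus attributes
#'   `rejected_short` counting pairs without enough common scans.
#' @export
group_by_correlation <- function(features, candidates = NULL,
                                 threshold = 0.9, min_scans = 4L) {
  if (is.null(candidates)) candidates <- find_candidates(features)
  n <- nrow(features)
  edges <- matrix(integer(), ncol = 2)
  cors <- numeric(0)
  rejected_short <- 0L
  if (nrow(candidates)) {
    keep <- logical(nrow(candidates))
    cors <- numeric(nrow(candidates))
    for (k in seq_len(nrow(candidates))) {
      i <- candidates$i[k]; j <- candidates$j[k]
      r <- .trace_correlation(features$trace[[i]], features$trace[[j]],
                              min_scans)
      cors[k] <- r
      if (is.na(r)) { rejected_short <- rejected_short + 1L; next }
      keep[k] <- r > threshold
    }
    edges <- cbind(candidates$i[keep], candidates$j[keep])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  groups <- lapply(sort(unique(comp)), function(cid) {
    members <- which(comp == cid)
    tot <- vapply(members, function(i) sum(features$trace[[i]]$intensity), 0)
    sub_cor <- matrix(NA_real_, length(members), length(members),
                      dimnames = list(features$feature_id[members],
                                      features$feature_id[members]))
    diag(sub_cor) <- 1
    if (nrow(candidates)) {
      for (k in seq_len(nrow(candidates))) {
        a <- match(candidates$i[k], members)
        b <- match(candidates$j[k], members)
        if (!is.na(a) && !is.na(b)) sub_cor[a, b] <- sub_cor[b, a] <- cors[k]
      }
    }
    list(members = members,
         feature_ids = features$feature_id[members],
         representative = members[which.max(tot)],
         consensus_rt = sum(features$rt_apex[members] * tot) / sum(tot),
         correlations = sub_cor)
  })
  structure(groups, class = "feature_groups", rejected_short = rejected_short)
}

# adduct / fragment mass differences used by the automated curation step
.ROLE_DELTAS <- c(
  "[M+NH4]+ vs [M+H]+" = 17.026549,
  "[M+Na]+ vs [M+H]+" = 21.981944,
  "[M+K]+ vs [M+H]+" = 37.955881,
  "[M+K]+ vs [M+Na]+" = 15.973937,
  "acetoxy-loss" = 60.021129
)

#' Annotate adduct and fragment roles within a group
#'
#' Automated surrogate for manual spectrum curation: the lowest-m/z member
#' is taken as the reference ion, members whose m/z difference from it (or
#' pairwise) matches a known adduct difference (Na-H, K-H, NH4-H) are
#' labeled accordingly, a pairwise difference of 60.0211 Da marks an
#' acetoxy-loss fragment pair, and unexplained members are labeled
#' `"unknown-related"`.
#'
#' @param group One element of a `feature_groups` list.
#' @param features The `peak_features` table the group indexes into.
#' @param tol Mass-difference tolerance, Da.
#' @return The group with a `roles` character vector (one per member) and
#'   `acetoxy_loss_pair` flag added.
#' @export
curate_group <- function(group, features, tol = 0.01) {
  members <- group$members
  if (length(members) == 1) {
    group$roles <- setNames("unassigned", group$feature_ids)
    group$acetoxy_loss_pair <- FALSE
    return(group)
  }
  mz <- features$mean_mz[members]
  roles <- rep("unknown-related", length(members))
  # acetoxy-loss pairs first: the lower-m/z member of a 60.0211 Da pair is
  # the fragment; the reference ion is then the lowest non-fragment m/z
  acetoxy <- FALSE
  is_fragment <- rep(FALSE, length(members))
  for (a in seq_along(members)) {
    for (b in seq_along(members)) {
      if (a == b) next
      if (abs((mz[b] - mz[a]) - .ROLE_DELTAS[["acetoxy-loss"]]) <= tol) {
        acetoxy <- TRUE
        is_fragment[a] <- TRUE
      }
    }
  }
  roles[is_fragment] <- "acetoxy-loss fragment"
  nonfrag <- which(!is_fragment)
  if (length(nonfrag)) {
    base <- nonfrag[which.min(mz[nonfrag])]
    roles[base] <- "[M+H]+ (reference)"
    for (k in setdiff(nonfrag, base)) {
      d <- mz[k] - mz[base]
      hit <- which(abs(.ROLE_DELTAS[1:3] - d) <= tol)
      if (length(hit)) {
        roles[k] <- sub(" vs .*", "", names(.ROLE_DELTAS)[hit[1]])
      }
    }
  }
  group$roles <- setNames(roles, features$feature_id[members])
  group$acetoxy_loss_pair <- acetoxy
  group
}

#' Write a group table as CSV
#' @param groups A curated `feature_groups` list.
#' @param path Output path.
#' @export
write_group_table <- function(groups, path) {
  rows <- lapply(seq_along(groups), function(g) {
    gr <- groups[[g]]
    data.frame(group_id = g,
               member_ids = paste(gr$feature_ids, collapse = ";"),
               roles = paste(gr$roles %||% "", collapse = ";"),
               consensus_rt = gr$consensus_rt,
               acetoxy_loss_pair = isTRUE(gr$acetoxy_loss_pair))
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}
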