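# Downstream statistics.
#
# Quantile normalization (ties averaged over the reference), natural-log
# transform with +1 offset on zeros, feature-wise centering and scaling;
# SVD-based PCA with samples as observations; divergent-feature selection
# from component loadings; LOWESS / stage-mean trend curves; one-way ANOVA
# with Tukey HSD compact letter display and Welch t-tests; signed
# fifth-power correlation heatmaps; and the seed dry-weight power-law model.

#' Quantile-normalize, log-transform, center and scale a feature matrix
#'
#' Columns (samples) are quantile-normalized to the mean sorted vector,
#' with ties receiving the mean of the tied-rank reference values; values
#' are then natural-log transformed (zeros offset by +1 count first) and
#' each feature row centered and scaled to unit variance. Constant rows are
#' centered but not scaled and flagged.
#'
#' @param mat Numeric matrix, features x samples, non-negative.
#' @param log_transform,center_scale Stage switches (all on by default).
#' @return Matrix of class `normalized_matrix` with attribute
#'   `constant_rows`.
#' @export
normalize_features <- function(mat, log_transform = TRUE,
                               center_scale = TRUE) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  qn <- quantile_normalize(mat)
  if (log_transform) {
    qn[qn == 0] <- 1
    qn <- log(qn)
  }
  constant <- logical(nrow(qn))
  if (center_scale) {
    for (i in seq_len(nrow(qn))) {
      v <- qn[i, ]
      s <- sd(v)
      if (s < 1e-12) {
        constant[i] <- TRUE
        qn[i, ] <- v - mean(v)
      } else {
        qn[i, ] <- (v - mean(v)) / s
      }
    }
  }
  structure(qn, class = c("normalized_matrix", class(qn)),
            constant_rows = which(constant))
}

#' Quantile normalization
#'
#' @param mat Features x samples matrix.
#' @return Matrix whose columns all share the identical sorted vector (the
#'   row-mean of the sorted columns); tied values receive the mean of the
#'   reference values at their tied ranks.
#' @export
quantile_normalize <- function(mat) {
  n <- nrow(mat)
  sorted <- apply(mat, 2, sort)
  ref <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    # non-integer (tied) ranks interpolate the reference
    out[, j] <- approx(seq_len(n), ref, xout = r, rule = 2)$y
  }
  out
}

#' Principal component analysis of a normalized matrix
#'
#' @param nm Features x samples matrix (already normalized; no further
#'   centering or scaling is applied).
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components, orthonormal), `variance_fraction`.
#' @export
run_pca <- function(nm) {
  stopifnot(ncol(nm) >= 3)
  p <- prcomp(t(nm), center = FALSE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation,
                 variance_fraction = vf),
            class = "pca_result")
}

#' Select divergent feature groups from component loadings
#'
#' Features whose |loading| on the chosen component exceeds the per-sign
#' `loading_quantile` are split by loading sign into a trend-up and a
#' trend-down set. If a set comes out empty the quantile is lowered
#' stepwise by 0.05 (logged via message) until non-empty or exhausted.
#'
#' @param pca A `pca_result`.
#' @param component Component index.
#' @param loading_quantile Per-sign quantile threshold (default 0.95).
#' @return List of class `selection_result`: `up`, `down` (feature
#'   indices; disjoint), `threshold_up`, `threshold_down`, `component`.
#' @export
select_divergent_groups <- function(pca, component = 1L,
                                    loading_quantile = 0.95) {
  ld <- pca$loadings[, component]
  pick <- function(v, q0) {
    q <- q0
    repeat {
      if (!length(v)) return(list(idx = integer(), thr = NA_real_))
      thr <- stats::quantile(abs(v), q, names = FALSE)
      idx <- which(abs(v) >= thr & abs(v) > 0)
      if (length(idx) || q <= 0.5) {
        if (!length(idx)) message("empty selection after quantile fallback")
        return(list(idx = idx, thr = thr))
      }
      q <- q - 0.05
      message(sprintf("empty selection; lowering loading quantile to %.2f", q))
    }
  }
  pos <- which(ld > 0); neg <- which(ld < 0)
  up <- pick(ld[pos], loading_quantile)
  dn <- pick(ld[neg], loading_quantile)
  structure(list(up = pos[up$idx], down = neg[dn$idx],
                 threshold_up = up$thr, threshold_down = dn$thr,
                 component = component),
            class = "selection_result")
}

#' Trend curves for feature groups
#'
#' @param nm Normalized features x samples matrix.
#' @param groups List of feature-index vectors (e.g. `up` / `down` from
#'   [select_divergent_groups()]).
#' @param covariate Numeric per-sample covariate (stage order or dry
#'   weight).
#' @param method `"lowess"` (span 0.6) or `"mean-by-stage"`; LOWESS falls
#'   back to stage means below 4 points.
#' @param span LOWESS span.
#' @return List of class `trend_result`: per group a `data.frame` with the
#'   sorted covariate and the smoothed group-mean response.
#' @export
trend_curves <- function(nm, groups, covariate,
                         method = c("lowess", "mean-by-stage"), span = 0.6) {
  method <- match.arg(method)
  stopifnot(length(covariate) == ncol(nm))
  out <- lapply(groups, function(idx) {
    y <- if (length(idx) > 1) colMeans(nm[idx, , drop = FALSE])
         else if (length(idx) == 1) nm[idx, ] else rep(NA_real_, ncol(nm))
    if (method == "lowess" && length(unique(covariate)) >= 4) {
      lw <- lowess(covariate, y, f = span)
      data.frame(covariate = lw$x, value = lw$y)
    } else {
      agg <- tapply(y, covariate, mean)
      data.frame(covariate = as.numeric(names(agg)), value = as.numeric(agg))
    }
  })
  structure(out, class = "trend_result", method = method)
}

#' One-way group tests: ANOVA, Tukey HSD letters, Welch t-test
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, >= 2 replicates each).
#' @param alpha Significance level for the letter display.
#' @return List: `anova_p`, `letters` (named by group, ordered by
#'   decreasing mean), `tukey` (pairwise table), `t_test_p` (for exactly
#'   two groups, Welch), `flag`.
#' @export
group_tests <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  if (all(tapply(values, groups, var) == 0) &&
      length(unique(values)) == 1) {
    return(list(anova_p = NA_real_, letters = NULL, tukey = NULL,
                t_test_p = NA_real_, flag = "zero variance"))
  }
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  anova_p <- an[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  letters <- tukey_letters(values, groups, alpha)
  t_p <- if (nlevels(groups) == 2) {
    sp <- split(values, groups)
    t.test(sp[[1]], sp[[2]])$p.value
  } else NA_real_
  list(anova_p = anova_p, letters = letters, tukey = tk, t_test_p = t_p,
       flag = NA_character_)
}

#' Compact letter display for Tukey HSD
#'
#' Groups are connected when their Tukey honestly-significant-difference
#' comparison is non-significant at `alpha`; letters are the maximal
#' cliques of that graph, ordered by decreasing group mean.
#'
#' @param values,groups Response and group labels.
#' @param alpha Significance level.
#' @return Named character vector of letter strings, one per group, ordered
#'   by decreasing group mean.
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  lv <- levels(groups)
  k <- length(lv)
  adj <- matrix(TRUE, k, k, dimnames = list(lv, lv))
  for (row in rownames(tk)) {
    pair <- strsplit(row, "-", fixed = TRUE)[[1]]
    # level names may themselves contain '-': split at every position and
    # keep the one matching two known levels
    if (length(pair) != 2 || !all(pair %in% lv)) {
      for (pos in seq_len(nchar(row) - 1)) {
        a <- substr(row, 1, pos); b <- substr(row, pos + 2, nchar(row))
        if (a %in% lv && b %in% lv &&
            substr(row, pos + 1, pos + 1) == "-") { pair <- c(a, b); break }
      }
    }
    sig <- tk[row, "p adj"] < alpha
    if (sig) adj[pair[1], pair[2]] <- adj[pair[2], pair[1]] <- FALSE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  means <- tapply(values, groups, mean)
  ord <- order(means, decreasing = TRUE)
  # order cliques by the best (highest) mean they contain
  cl_rank <- vapply(cliques, function(cl)
    min(match(lv[as.integer(cl)], lv[ord])), 0)
  cliques <- cliques[order(cl_rank)]
  letter_of <- setNames(rep("", k), lv)
  for (i in seq_along(cliques)) {
    for (v in lv[as.integer(cliques[[i]])]) {
      letter_of[v] <- paste0(letter_of[v], letters[i])
    }
  }
  letter_of[lv[ord]]
}

#' Signed fifth-power correlation heatmap matrix
#'
#' Entries are `sign(r) * |r|^5` (the odd power preserves sign while
#' flattening weak correlations); rows and columns are ordered by
#' average-linkage hierarchical clustering on correlation distance.
#' Constant rows yield masked (NA) entries.
#'
#' @param a,b Matrices with features in rows and the same samples in
#'   columns (>= 3 shared samples).
#' @return List of class `correlation_heatmap`: `r5` (rows of `a` x rows
#'   of `b`), `row_order`, `col_order`.
#' @export
correlation_heatmap <- function(a, b = a) {
  stopifnot(ncol(a) == ncol(b), ncol(a) >= 3)
  const_a <- apply(a, 1, sd) == 0
  const_b <- apply(b, 1, sd) == 0
  r <- suppressWarnings(cor(t(a), t(b)))
  r[const_a, ] <- NA
  r[, const_b] <- NA
  r5 <- sign(r) * abs(r)^5
  row_order <- .hclust_order(a)
  col_order <- .hclust_order(b)
  structure(list(r5 = r5, row_order = row_order, col_order = col_order),
            class = "correlation_heatmap")
}

.hclust_order <- function(m) {
  ok <- which(apply(m, 1, sd) > 0)
  if (length(ok) < 3) return(seq_len(nrow(m)))
  d <- as.dist(1 - cor(t(m[ok, , drop = FALSE])))
  h <- hclust(d, method = "average")
  c(ok[h$order], setdiff(seq_len(nrow(m)), ok))
}

#' Fit the seed dry-weight power-law model
#'
#' Fits `TAC = a * DW^b`. The default method is nonlinear least squares on
#' the original scale, initialized from the log-log linear fit; `"loglog"`
#' is the spreadsheet-trendline estimator (ordinary least squares of
#' log TAC on log DW), the appropriate estimator under multiplicative
#' lognormal noise. R-squared is always computed on the original scale.
#'
#' @param dw,tac Positive dry weights and total acetogenin concentrations.
#' @param method `"nls"` or `"loglog"`.
#' @return List of class `power_law_fit`: `a`, `b`, `r_squared`, `method`,
#'   `converged`.
#' @export
fit_power_law <- function(dw, tac, method = c("nls", "loglog")) {
  method <- match.arg(method)
  stopifnot(length(dw) == length(tac))
  if (any(dw <= 0) || any(tac <= 0))
    stop("power-law fit requires positive dry weights and concentrations")
  ll <- lm(log(tac) ~ log(dw))
  a0 <- exp(coef(ll)[[1]]); b0 <- coef(ll)[[2]]
  converged <- TRUE
  if (method == "nls") {
    fit <- tryCatch(
      nls(tac ~ a * dw^b, start = list(a = a0, b = b0),
          control = list(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      method <- "loglog"; converged <- FALSE
      a <- a0; b <- b0
    } else {
      a <- coef(fit)[["a"]]; b <- coef(fit)[["b"]]
    }
  }
  if (method == "loglog") { a <- a0; b <- b0 }
  pred <- a * dw^b
  r2 <- 1 - sum((tac - pred)^2) / sum((tac - mean(tac))^2)
  structure(list(a = a, b = b, r_squared = r2, method = method,
                 converged = converged),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> TAC = %.3g * DW^%.4g (R^2 = %.3f, %s)\n",
              x$a, x$b, x$r_squared, x$method))
  invisible(x)
}

#' Predict TAC from one principal-component score
#'
#' Ordinary least squares of the total acetogenin concentration on a single
#' score vector.
#'
#' @param scores Per-sample component scores.
#' @param tac Per-sample TAC.
#' @return List: `r_squared`, `slope`, `intercept`.
#' @export
predict_tac_from_pc <- function(scores, tac) {
  fit <- lm(tac ~ scores)
  list(r_squared = summary(fit)$r.squared,
       slope = coef(fit)[[2]], intercept = coef(fit)[[1]])
}
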