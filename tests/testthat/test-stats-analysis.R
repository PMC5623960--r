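# stats-analysis module: normalization, PCA, selection, trends, group
# tests, correlation heatmaps, power law.

test_that("quantile normalization matches its definition and limma", {
  set.seed(10)
  m <- matrix(rexp(120 * 5, 1 / 500), 120, 5)
  qn <- quantile_normalize(m)
  ref <- rowMeans(apply(m, 2, sort))
  for (j in 1:5) expect_equal(sort(qn[, j]), ref, tolerance = 1e-12)
  # idempotence
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  # identical samples unchanged
  m2 <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(quantile_normalize(m2), m2, tolerance = 1e-12)
  # a monotone distortion of one sample is removed (rank-preserving)
  m3 <- cbind(a = m[, 1], b = m[, 1]^1.7 * 3)
  qn3 <- quantile_normalize(m3)
  expect_equal(qn3[, "a"], qn3[, "b"], tolerance = 1e-9,
               ignore_attr = TRUE)
  # independent oracle: limma with tie averaging
  mt <- m; mt[1:10, ] <- mt[1, 1]  # inject ties
  expect_equal(quantile_normalize(mt),
               limma::normalizeQuantiles(mt, ties = TRUE),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("normalization pipeline centers, scales and flags", {
  set.seed(11)
  m <- matrix(rexp(50 * 4, 1 / 100), 50, 4)
  m[7, ] <- 0        # all-zero feature: offset then constant
  nm <- normalize_features(m)
  expect_equal(rowMeans(nm), rep(0, 50), tolerance = 1e-9)
  live <- setdiff(seq_len(50), attr(nm, "constant_rows"))
  expect_equal(apply(nm[live, ], 1, sd), rep(1, length(live)),
               tolerance = 1e-9)
  expect_true(7 %in% attr(nm, "constant_rows"))
})

test_that("PCA is orthonormal and recovers an injected trend", {
  set.seed(12)
  stage <- 1:8
  n_feat <- 60
  m <- matrix(rnorm(n_feat * 8, sd = 0.05), n_feat, 8)
  m[1:30, ] <- m[1:30, ] + outer(rep(1, 30), scale(stage)[, 1]) * 3
  nm <- structure(t(scale(t(m))), class = "matrix")
  p <- run_pca(nm)
  k <- min(dim(p$loadings))
  expect_equal(crossprod(p$loadings[, 1:k]), diag(k), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(p$variance_fraction) < 1e-9))
  expect_lte(sum(p$variance_fraction), 1 + 1e-9)
  # PC1 scores ordered by the injected stage trend (up to sign)
  sc <- p$scores[, 1] * sign(cor(p$scores[, 1], stage))
  expect_equal(order(sc), order(stage))
  # feature-permutation invariance of scores up to sign
  perm <- sample(n_feat)
  p2 <- run_pca(nm[perm, ])
  agree <- abs(cor(p$scores[, 1], p2$scores[, 1]))
  expect_equal(agree, 1, tolerance = 1e-9)
})

test_that("divergent-group selection enriches true trend classes", {
  set.seed(13)
  n_up <- 50; n_dn <- 50; n_flat <- 900; ns <- 9
  stage <- seq_len(ns)
  z <- scale(stage)[, 1]
  m <- rbind(
    outer(rep(1, n_up), z) * 2 + rnorm(n_up * ns, sd = 0.3),
    outer(rep(1, n_dn), -z) * 2 + rnorm(n_dn * ns, sd = 0.3),
    matrix(rnorm(n_flat * ns, sd = 0.3), n_flat, ns)
  )
  nm <- structure(t(scale(t(m))), class = "matrix")
  p <- run_pca(nm)
  sel <- select_divergent_groups(p, 1)
  # orient: "up" should collect the up-trending block
  s1 <- sign(cor(p$scores[, 1], stage))
  up_set <- if (s1 > 0) sel$up else sel$down
  dn_set <- if (s1 > 0) sel$down else sel$up
  expect_gt(length(up_set), 0)
  expect_gt(length(dn_set), 0)
  expect_gte(mean(up_set <= n_up), 0.9)
  expect_gte(mean(dn_set > n_up & dn_set <= n_up + n_dn), 0.9)
  expect_equal(length(intersect(sel$up, sel$down)), 0)
  # sign flip swaps the sets exactly
  pflip <- p
  pflip$loadings[, 1] <- -p$loadings[, 1]
  pflip$scores[, 1] <- -p$scores[, 1]
  self <- select_divergent_groups(pflip, 1)
  expect_setequal(self$up, sel$down)
  expect_setequal(self$down, sel$up)
})

test_that("trend curves smooth monotone and constant inputs sanely", {
  x <- 1:12
  m <- rbind(inc = x / 3, const = rep(2, 12))
  tr <- trend_curves(m, list(inc = 1, const = 2), covariate = x)
  expect_true(all(diff(tr[[1]]$value) >= -1e-9))
  expect_true(all(abs(diff(tr[[2]]$value)) < 1e-9))
  # plateau input reaches >= 95% of its maximum by the saturation point
  sat <- pmin(x, 8) / 8
  trs <- trend_curves(rbind(sat), list(1), covariate = x)
  v <- trs[[1]]
  expect_gte(max(v$value[v$covariate >= 8]), 0.95 * max(v$value))
  # too few points fall back to stage means
  short <- trend_curves(rbind(c(1, 2, 3)), list(1), covariate = c(1, 1, 2))
  expect_equal(attr(short, "method"), "lowess")
  expect_equal(nrow(short[[1]]), 2)
})

test_that("group tests produce ANOVA, letters and Welch p-values", {
  set.seed(14)
  v <- c(rnorm(3, 10, 1), rnorm(3, 100, 1))
  g <- rep(c("low", "high"), each = 3)
  gt <- group_tests(v, g)
  expect_lt(gt$anova_p, 0.001)
  expect_equal(length(unique(gt$letters)), 2)
  expect_lt(gt$t_test_p, 0.01)
  # identical groups share a letter
  v2 <- rep(c(5, 6, 7), 2)
  gt2 <- group_tests(v2, rep(c("a1", "a2"), each = 3))
  expect_equal(length(unique(gt2$letters)), 1)
  # three groups, one separated: separated group has a unique letter
  v3 <- c(rnorm(4, 0, 1), rnorm(4, 0.3, 1), rnorm(4, 60, 1))
  g3 <- rep(c("g1", "g2", "g3"), each = 4)
  lt3 <- tukey_letters(v3, g3)
  expect_false(lt3[["g3"]] %in% lt3[c("g1", "g2")])
  expect_true(any(grepl(substr(lt3[["g1"]], 1, 1), lt3[["g2"]])))
  # zero-variance flag
  gt0 <- group_tests(rep(1, 6), rep(c("u", "w"), each = 3))
  expect_equal(gt0$flag, "zero variance")
})

test_that("Tukey letters agree with a brute-force studentized-range oracle", {
  set.seed(15)
  for (case in 1:12) {
    k <- sample(3:5, 1)
    n <- sample(3:5, 1)
    mu <- sample(c(0, 0.5, 3, 20, 40), k)
    v <- as.vector(vapply(mu, function(m) rnorm(n, m, 1), numeric(n)))
    g <- factor(rep(paste0("grp", seq_len(k)), each = n))
    lt <- tukey_letters(v, g)
    # oracle: pairwise studentized-range p-values from first principles
    fit <- aov(v ~ g)
    mse <- sum(resid(fit)^2) / fit$df.residual
    means <- tapply(v, g, mean)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      qstat <- abs(means[i] - means[j]) / sqrt(mse / n)
      p <- 1 - ptukey(qstat, k, fit$df.residual)
      share <- any(strsplit(lt[[levels(g)[i]]], "")[[1]] %in%
                     strsplit(lt[[levels(g)[j]]], "")[[1]])
      if (p < 0.05) expect_false(share) else expect_true(share)
    }
  }
})

test_that("correlation heatmap applies the signed fifth power", {
  x <- c(1, 2, 3, 4, 5)
  # construct a vector with exact correlation 0.5 to x
  zx <- scale(x)[, 1]
  orth <- scale(c(1, -1, 2, -2, 0) -
                  zx * sum(zx * c(1, -1, 2, -2, 0)) / sum(zx^2))[, 1]
  y <- 0.5 * zx + sqrt(0.75) * orth
  expect_equal(cor(x, y), 0.5, tolerance = 1e-12)
  hm <- correlation_heatmap(rbind(a = x, b = -x, c = y))
  expect_equal(hm$r5["a", "a"], 1)
  expect_equal(hm$r5["a", "b"], -1)
  expect_equal(hm$r5["a", "c"], 0.5^5, tolerance = 1e-9)
  expect_equal(hm$r5["b", "c"], -0.5^5, tolerance = 1e-9)
  # constant rows masked
  hm2 <- correlation_heatmap(rbind(a = x, k = rep(1, 5)))
  expect_true(all(is.na(hm2$r5["k", ])))
  # anti-correlated blocks are strongly negative across classes
  set.seed(16)
  up <- outer(rep(1, 4), 1:8) + rnorm(32, sd = 0.1)
  dn <- outer(rep(1, 4), 8:1) + rnorm(32, sd = 0.1)
  hm3 <- correlation_heatmap(up, dn)
  expect_lt(max(hm3$r5), -0.5)
})

test_that("power-law fitting recovers parameters and falls back", {
  d <- generate_seed_growth_series(noise_cv = 0, seed = 3)
  f <- fit_power_law(d$dry_weight, d$tac)
  expect_equal(f$b, 2.246, tolerance = 1e-3)
  expect_equal(f$a, 32.7, tolerance = 1e-3)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # linear data recover b ~ 1
  x <- seq(0.2, 2, length.out = 15)
  fl <- fit_power_law(x, 5 * x)
  expect_equal(fl$b, 1, tolerance = 1e-6)
  # pure noise: R^2 near zero
  set.seed(17)
  fn <- fit_power_law(runif(40, 0.5, 1.5), rlnorm(40))
  expect_lt(fn$r_squared, 0.2)
  expect_error(fit_power_law(c(-1, 2), c(1, 2)), "positive")
  # recovery property at the generator default noise (log-space estimator,
  # the spreadsheet-trendline method; see vignette)
  errs <- vapply(1:200, function(r) {
    d <- generate_seed_growth_series(seed = r)
    abs(fit_power_law(d$dry_weight, d$tac, method = "loglog")$b - 2.246)
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("TAC is predictable from a PC score", {
  set.seed(18)
  score <- rnorm(12)
  tac <- 2 + 3 * score + rnorm(12, sd = 0.1)
  pr <- predict_tac_from_pc(score, tac)
  expect_gt(pr$r_squared, 0.9)
  expect_equal(pr$slope, 3, tolerance = 0.2)
})
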