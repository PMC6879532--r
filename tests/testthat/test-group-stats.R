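test_that("Levene gate and t-test agree with reference implementations", {
  set.seed(30)
  for (i in 1:20) {
    g1 <- rnorm(25, sd = sample(c(1, 3), 1))
    g2 <- rnorm(14, sd = 1)
    row <- leveneGatedTTest(g1, g2)
    lev <- car::leveneTest(c(g1, g2),
                           factor(rep(1:2, c(25, 14))), center = mean)
    expect_equal(row$levene_F, lev[1, "F value"], tolerance = 1e-10)
    expect_equal(row$levene_p, lev[1, "Pr(>F)"], tolerance = 1e-10)
    ref <- stats::t.test(g1, g2, var.equal = row$variant == "pooled")
    expect_equal(row$t, unname(ref$statistic))
    expect_equal(row$df, unname(ref$parameter))
    expect_equal(c(row$ci_lo, row$ci_hi), as.numeric(ref$conf.int))
    expect_equal(row$diff, mean(g1) - mean(g2))
    expect_true(row$ci_lo <= row$diff && row$diff <= row$ci_hi)
  }
})

test_that("identical groups give a null comparison", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  row <- leveneGatedTTest(x, x)
  expect_equal(row$t, 0)
  expect_equal(row$diff, 0)
  expect_error(leveneGatedTTest(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("per-tail trimming before testing drops floor(trim n) per side", {
  g1 <- c(rep(10, 18), -1e6, 1e6)
  g2 <- rnorm(20, 10)
  row <- leveneGatedTTest(g1, g2, trim = 0.05)
  expect_equal(row$mean1, 10)                     # outliers trimmed away
  expect_equal(row$sd1, 0)
})

test_that("Dunn-Bonferroni decisions match the p-value inequality", {
  db1 <- dunnBonferroni(2, m = 1, df = 30)
  expect_equal(db1$criticalT, qt(0.975, 30))
  set.seed(31)
  for (i in 1:50) {
    m <- sample(2:12, 1); df <- sample(10:100, 1)
    tv <- rt(m, df) * 2
    db <- dunnBonferroni(tv, m, df)
    byP <- 2 * pt(-abs(tv), df) <= 0.05 / m + 1e-12
    expect_equal(db$significant, byP)
  }
  allsmall <- dunnBonferroni(c(0.2, -0.5, 1.1), m = 9, df = 71)
  expect_false(any(allsmall$significant))
  expect_error(dunnBonferroni(1, 9, df = -1), "df")
})

test_that("Mahalanobis screening keeps the centroid and drops planted outliers", {
  set.seed(32)
  X <- matrix(rnorm(72 * 9), 72, 9)
  X <- rbind(X, colMeans(X))
  rownames(X) <- sprintf("P%02d", 1:73)
  sc <- mahalanobisScreen(X)
  expect_equal(unname(sc$distances[73]), 0, tolerance = 1e-10)
  expect_false("P73" %in% sc$excludedIds)
  Y <- X; Y[5, ] <- Y[5, ] + 10
  sc2 <- mahalanobisScreen(Y)
  expect_true("P05" %in% sc2$excludedIds)
  expect_equal(sc2$cutoff, qchisq(0.999, 9))
  sing <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(mahalanobisScreen(sing), "singular")
  expect_error(mahalanobisScreen(X[1:5, ]), "more rows")
})

test_that("Mahalanobis exclusions are calibrated under multivariate normality", {
  set.seed(33)
  total <- 0
  for (r in 1:50) {
    X <- matrix(rnorm(500 * 9), 500, 9)
    rownames(X) <- sprintf("S%03d", 1:500)
    total <- total + length(mahalanobisScreen(X)$excludedIds)
  }
  # 50 reps x E[0.5] exclusions: Poisson(25) central 95% band
  expect_gte(total, qpois(0.025, 25))
  expect_lte(total, qpois(0.975, 25))
})

test_that("mixed ANOVA reproduces aov error strata exactly", {
  set.seed(34)
  for (rep in 1:5) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1); k <- sample(3:5, 1)
    y <- matrix(rnorm((n1 + n2) * k), n1 + n2, k)
    g <- rep(c("a", "b"), c(n1, n2))
    r <- mixedAnova(y, g)
    d <- data.frame(y = as.vector(y),
                    s = factor(rep(seq_len(n1 + n2), k)),
                    task = factor(rep(seq_len(k), each = n1 + n2)),
                    g = factor(rep(g, k)))
    a <- summary(stats::aov(y ~ g * task + Error(s / task), data = d))
    tab1 <- a[["Error: s"]][[1]]
    tab2 <- a[["Error: s:task"]][[1]]
    expect_equal(r$effects$SS, c(tab1["g", "Sum Sq"],
                                 tab2["task", "Sum Sq"],
                                 tab2["g:task", "Sum Sq"]),
                 tolerance = 1e-10)
    expect_equal(r$effects$F, c(tab1["g", "F value"],
                                tab2["task", "F value"],
                                tab2["g:task", "F value"]),
                 tolerance = 1e-10)
    expect_equal(r$effects$p, c(tab1["g", "Pr(>F)"],
                                tab2["task", "Pr(>F)"],
                                tab2["g:task", "Pr(>F)"]),
                 tolerance = 1e-10)
  }
})

test_that("Mauchly statistic matches stats::mauchly.test", {
  set.seed(35)
  y <- matrix(rnorm(40 * 4), 40) %*% chol(0.4 * diag(4) + 0.6)
  g <- rep(c("a", "b"), each = 20)
  r <- mixedAnova(y, g)
  m <- stats::mauchly.test(lm(y ~ factor(g)), X = ~1,
                           idata = data.frame(task = factor(1:4)))
  expect_equal(r$mauchly$W, unname(m$statistic), tolerance = 1e-8)
  expect_equal(r$mauchly$p, m$p.value, tolerance = 1e-8)
})

test_that("sphericity handling: epsilon bounds and GG gating", {
  set.seed(36)
  # compound symmetry: epsilon near 1, no adjustment
  S <- 0.5 * diag(9) + 0.5
  y <- matrix(rnorm(400 * 9), 400) %*% chol(S)
  r <- mixedAnova(y, rep(c("a", "b"), each = 200))
  expect_gt(r$epsilon, 0.97)
  expect_false(r$ggApplied)
  # adversarial covariance: epsilon respects its analytic lower bound
  v <- c(100, rep(0.01, 8))
  y2 <- sweep(matrix(rnorm(60 * 9), 60), 2, sqrt(v), "*")
  r2 <- mixedAnova(y2, rep(c("a", "b"), each = 30))
  expect_gte(r2$epsilon, 1 / 8)
  expect_lte(r2$epsilon, 1)
  expect_true(r2$ggApplied)
  expect_equal(r2$effects$df1_adj[2], r2$epsilon * 8)
  # partial eta squared stays in [0, 1]
  expect_true(all(r2$effects$partialEta2 >= 0 &
                  r2$effects$partialEta2 <= 1))
})

test_that("mixed ANOVA refuses degenerate designs and logs listwise removal", {
  y <- matrix(rnorm(20 * 3), 20)
  expect_error(mixedAnova(y, rep("a", 20)), "two groups")
  expect_error(mixedAnova(y[, 1, drop = FALSE], rep(c("a", "b"), 10)),
               "within-subject levels")
  y[3, 2] <- NA
  r <- mixedAnova(y, rep(c("a", "b"), 10))
  expect_equal(r$nExcluded, 1L)
  expect_equal(r$nSubjects, 19L)
})

test_that("KMO/Bartlett diagnostics follow their closed forms", {
  idr <- kmoBartlett(diag(9), n = 73)
  expect_equal(idr$bartlettChisq, 0)
  expect_equal(idr$bartlettDf, 36)
  # equicorrelation: determinant has a closed form
  rho <- 0.5; p <- 9; n <- 73
  R <- (1 - rho) * diag(p) + rho
  eq <- kmoBartlett(R, n = n)
  detR <- (1 - rho)^(p - 1) * (1 + (p - 1) * rho)
  expect_equal(eq$bartlettChisq, -(n - 1 - (2 * p + 5) / 6) * log(detR),
               tolerance = 1e-10)
  set.seed(37)
  X <- matrix(rnorm(200 * 9), 200) %*% chol(R)
  k <- kmoBartlett(X)
  expect_true(k$kmo > 0 && k$kmo < 1)
  expect_lt(k$bartlettP, 1e-6)
  expect_error(kmoBartlett(matrix(1, 3, 3), n = 10), "positive definite")
})

test_that("varimax PCA recovers a planted two-factor structure", {
  set.seed(38)
  L <- matrix(0, 9, 2)
  L[1:5, 1] <- 0.8
  L[6:9, 2] <- 0.8
  F <- matrix(rnorm(500 * 2), 500)
  X <- F %*% t(L) + matrix(rnorm(500 * 9), 500) %*%
    diag(sqrt(1 - rowSums(L^2)))
  colnames(X) <- paste0("V", 1:9)
  p <- pcaVarimax(X, eigenCutoff = 0.80)
  expect_equal(p$nRetained, 2L)
  # match components to planted factors by dominant loading
  est <- p$loadings
  o <- if (mean(abs(est[1:5, 1])) > mean(abs(est[1:5, 2]))) 1:2 else 2:1
  expect_lt(max(abs(abs(est[, o]) - L)), 0.1)
  expect_true(p$totalVariancePct > 0 && p$totalVariancePct < 100)
})

test_that("an already varimax-optimal solution is a rotation fixed point", {
  L <- matrix(0, 6, 2)
  L[1:3, 1] <- c(0.9, 0.8, 0.7)
  L[4:6, 2] <- c(0.9, 0.8, 0.7)
  vm <- stats::varimax(L, normalize = TRUE, eps = 1e-6)
  expect_equal(abs(vm$rotmat), diag(2), tolerance = 1e-4)
})

test_that("spherical data retain all components with a warning", {
  set.seed(39)
  X <- matrix(rnorm(400 * 9), 400)
  expect_warning(p <- pcaVarimax(X, eigenCutoff = 0.80), "spherical")
  expect_equal(p$nRetained, 9L)
  expect_error(pcaVarimax(X, eigenCutoff = 1e6), "no component")
})

test_that("Anderson-Rubin scores are standardized and recover the factors", {
  set.seed(40)
  L <- matrix(0, 9, 2); L[1:5, 1] <- 0.8; L[6:9, 2] <- 0.8
  F <- matrix(rnorm(500 * 2), 500)
  X <- F %*% t(L) + matrix(rnorm(500 * 9), 500) %*%
    diag(sqrt(1 - rowSums(L^2)))
  p <- pcaVarimax(X)
  s <- andersonRubinScores(X, p$loadings)
  expect_equal(max(abs(colMeans(s))), 0, tolerance = 1e-10)
  expect_equal(cov(s), diag(ncol(s)), tolerance = 1e-6, ignore_attr = TRUE)
  rmax <- apply(abs(cor(F, s)), 1, max)
  expect_true(all(rmax > 0.8))
  # single component reduces to a z-scored variate
  p1 <- pcaVarimax(X[, 1:5], eigenCutoff = 2)
  s1 <- andersonRubinScores(X[, 1:5], p1$loadings)
  expect_equal(ncol(s1), 1L)
  expect_equal(sd(s1[, 1]), 1, tolerance = 1e-10)
})

test_that("component ANOVA needs exactly two components and skips sphericity", {
  set.seed(41)
  s <- matrix(rnorm(40 * 2), 40)
  r <- componentMixedAnova(s, rep(c("a", "b"), 20))
  expect_null(r$mauchly)
  expect_equal(r$epsilon, 1)
  expect_false(r$ggApplied)
  expect_error(componentMixedAnova(matrix(rnorm(60), 20, 3),
                                   rep(c("a", "b"), 10)), "two components")
})

test_that("a component-specific group effect surfaces in the interaction", {
  set.seed(42)
  hits <- 0
  for (r in 1:100) {
    n1 <- 20; n2 <- 20
    s <- matrix(rnorm((n1 + n2) * 2), n1 + n2)
    s[(n1 + 1):(n1 + n2), 2] <- s[(n1 + 1):(n1 + n2), 2] + 2
    a <- componentMixedAnova(s, rep(c("x", "y"), c(n1, n2)))
    if (a$effects$p[3] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
  # identical groups: all effects behave like null draws
  set.seed(43)
  s0 <- matrix(rnorm(80), 40)
  a0 <- componentMixedAnova(s0, rep(c("x", "y"), 20))
  expect_true(all(a0$effects$p > 0.001))
})
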