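smallData <- function(n = 40, p = 2, delta = 1.5, seed = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(0L, 1L), each = n / 2)
    X[y == 1L, 1] <- X[y == 1L, 1] + delta
    colnames(X) <- sprintf("f%03d", seq_len(p))
    list(X = X, y = y)
  })
}

test_that("linear predictors and posteriors follow the logistic link", {
  beta <- setNames(numeric(3), c("a", "b", "c"))
  m0 <- new("DiscriminativeModel", alpha = 0, beta = beta, lambda = 0.1,
            fitMeta = list())
  lp <- linearPredictor(m0, c(1, 2, 3))
  expect_identical(lp$eta, 0)
  expect_identical(lp$posterior, 0.5)
  m1 <- new("DiscriminativeModel", alpha = log(3), beta = beta,
            lambda = 0, fitMeta = list())
  expect_equal(linearPredictor(m1, c(0, 0, 0))$posterior, 0.75)
  etas <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(sigmoid(etas)) > 0))
  expect_error(linearPredictor(m0, c(1, 2)), "does not match")
})

test_that("the penalty grid starts at an all-zero fit and decreases", {
  d <- smallData(60, 5)
  g <- lambdaGrid(d$X, d$y, nValues = 25, decades = 3)
  expect_length(g, 25)
  expect_true(all(diff(g) < 0))
  expect_equal(g[1] / g[25], 10^3)
  f <- fitL1Logistic(d$X, d$y, lambda = g[1])
  expect_true(all(modelCoefficients(f$model) == 0))
  expect_equal(modelIntercept(f$model), qlogis(mean(d$y)),
               tolerance = 1e-6)
})

test_that("the unpenalized fit matches a Newton-Raphson oracle to 1e-6", {
  for (seed in 1:3) {
    d <- smallData(40, 2, delta = 1.2, seed = seed)
    fit <- fitL1Logistic(d$X, d$y, lambda = 0, tol = 1e-15)
    ref <- newtonLogisticOracle(d$X, d$y)
    expect_lt(abs(modelIntercept(fit$model) - ref$alpha), 1e-6)
    expect_lt(max(abs(unname(modelCoefficients(fit$model)) - ref$beta)),
              1e-6)
  }
})

test_that("the objective trace is non-increasing and residuals bounded", {
  d <- smallData(80, 6)
  f <- fitL1Logistic(d$X, d$y, lambda = 0.02)
  expect_true(all(diff(f$objectiveTrace) <= 1e-12))
  expect_true(all(f$residuals > -1 & f$residuals < 1))
  expect_error(fitL1Logistic(d$X, rep(1L, 80), lambda = 0.1),
               "both classes")
})

test_that("a perfectly separating feature drives training AUC to 1", {
  withr::with_seed(4, {
    X <- cbind(f001 = c(rnorm(20, -3), rnorm(20, 3)),
               f002 = rnorm(40))
    y <- rep(c(0L, 1L), each = 20)
  })
  f <- fitL1Logistic(X, y, lambda = 0.01)
  eta <- linearPredictor(f$model, X)$eta
  expect_equal(rocAuc(eta, y)$auc, 1)
})

test_that("the fitted coefficient shrinks monotonically to zero in lambda", {
  d <- smallData(100, 1, delta = 2, seed = 9)
  lams <- c(0.001, 0.01, 0.05, 0.1, 0.2, lambdaMax(d$X, d$y))
  betas <- vapply(lams, function(l)
    unname(modelCoefficients(fitL1Logistic(d$X, d$y, lambda = l)$model)),
    numeric(1))
  expect_true(all(diff(betas) <= 1e-10))
  expect_true(all(betas >= 0))
  expect_equal(betas[length(betas)], 0)
})

test_that("the solver agrees with glmnet along the path", {
  skip_if_not_installed("glmnet")
  d <- smallData(200, 20, delta = 1, seed = 12)
  g <- lambdaGrid(d$X, d$y, nValues = 30, decades = 2)
  lams <- g[c(5, 15, 25)]
  gf <- glmnet::glmnet(d$X, d$y, family = "binomial", lambda = lams,
                       standardize = FALSE, thresh = 1e-13, maxit = 1e6)
  for (i in seq_along(lams)) {
    mf <- fitL1Logistic(d$X, d$y, lambda = lams[i], tol = 1e-12)
    expect_lt(max(abs(as.numeric(gf$beta[, i]) -
                        unname(modelCoefficients(mf$model)))), 1e-5)
    expect_lt(abs(as.numeric(gf$a0[i]) - modelIntercept(mf$model)), 1e-5)
  }
})

test_that("ROC/AUC handles ties, and the curve is a proper step function", {
  r <- rocAuc(c(0.9, 0.8, 0.3), c(1, 0, 1))
  expect_equal(r$auc, 0.5)
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(14, {
    for (i in 1:25) {
      n <- sample(5:40, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      r <- rocAuc(scores, labels)
      expect_equal(r$auc, aucPairsOracle(scores, labels))
      expect_identical(c(r$fpr[1], r$tpr[1]), c(0, 0))
      expect_identical(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]),
                       c(1, 1))
      expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
      # trapezoid under the step curve equals the U-statistic AUC
      trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
      expect_equal(trap, r$auc)
    }
  })
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(15, {
    scores <- rnorm(60)
    labels <- rbinom(60, 1, 0.5)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(scores, labels)$auc, ref)
})

test_that("the U test is exact for small samples and respects ties", {
  r <- featureUTest(c(3, 4, 5), c(0, 1, 2), "greater")
  expect_equal(r$p, 1 / 20)
  expect_equal(r$U, 9)
  same <- featureUTest(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_equal(same$U, 9 / 2)
  # swapping samples flips the exact one-sided p up to the point mass
  withr::with_seed(16, {
    for (i in 1:10) {
      x <- sample(0:5, 4, replace = TRUE)
      y <- sample(0:5, 5, replace = TRUE)
      pg <- featureUTest(x, y, "greater")$p
      expect_equal(pg, uGreaterOracle(x, y))
      pl <- featureUTest(x, y, "less")$p
      n1 <- 4; n2 <- 5
      U <- featureUTest(x, y, "greater")$U
      # P(U >= u) + P(U <= u) = 1 + P(U = u)
      combs <- combn(9, 4)
      pool <- c(x, y)
      rk <- rank(pool)
      Uperm <- apply(combs, 2, function(idx)
        sum(rk[idx]) - n1 * (n1 + 1) / 2)
      expect_equal(pg + pl, 1 + mean(abs(Uperm - U) < 1e-9))
    }
  })
})

test_that("the large-sample U test matches the tie-corrected normal form", {
  withr::with_seed(18, {
    x <- round(rnorm(30, 0.4), 1)
    y <- round(rnorm(25), 1)
  })
  r <- featureUTest(x, y, "greater")
  ref <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                      exact = FALSE, correct = FALSE))
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  expect_equal(r$U, unname(ref$statistic))
  expect_error(featureUTest(numeric(0), y), "non-empty")
})

test_that("nested CV returns exactly K folds and is seed-deterministic", {
  tab <- generateFeatureTable(effectSpec(nFeatures = 40,
                                         shiftedIndices = 1L, delta = 2),
                              60, seed = 19)
  ds <- buildDataset(tab[tab$genotype == "WT", ],
                     tab[tab$genotype == "MUT", ])
  res <- nestedCV(ds, K = 5L, innerK = 5L, nLambda = 30L, seed = 2)
  expect_length(res$foldAucs, 5)
  expect_length(res$lambdas, 5)
  expect_length(res$selected, 5)
  expect_equal(res$meanAuc, mean(res$foldAucs))
  res2 <- nestedCV(ds, K = 5L, innerK = 5L, nLambda = 30L, seed = 2)
  expect_identical(res$foldAucs, res2$foldAucs)
  expect_error(nestedCV(ds, K = 40L), "at least")
})

test_that("the learning curve reproduces nested CV at fraction one", {
  tab <- generateFeatureTable(effectSpec(nFeatures = 30,
                                         shiftedIndices = 2L, delta = 2),
                              50, seed = 23)
  ds <- buildDataset(tab[tab$genotype == "WT", ],
                     tab[tab$genotype == "MUT", ])
  lc <- learningCurve(ds, fractions = 1, repeats = 1, seed = 7, K = 5L,
                      innerK = 5L, nLambda = 20L)
  ref <- nestedCV(ds, K = 5L, innerK = 5L, nLambda = 20L,
                  seed = childSeed(7, 1))
  expect_equal(lc$mean_auc, ref$meanAuc)
  expect_identical(lc$n, 100L)
  expect_warning(
    lc2 <- learningCurve(ds, fractions = c(0.05, 1), repeats = 1,
                         seed = 7, K = 5L, innerK = 5L, nLambda = 20L),
    "skipped")
  expect_identical(nrow(lc2), 1L)
})

test_that("model JSON round trip restores the sparse coefficients", {
  d <- smallData(60, 8)
  f <- fitL1Logistic(d$X, d$y, lambda = 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(f$model, path, genotype = "PSMB5")
  back <- readModelJSON(path)
  expect_equal(modelCoefficients(back), modelCoefficients(f$model))
  expect_equal(modelIntercept(back), modelIntercept(f$model))
  expect_equal(back@lambda, f$model@lambda)
  expect_identical(back@fitMeta$genotype, "PSMB5")
})

test_that("filter preprocessing experiment tabulates one row per kind", {
  crops <- toyCropClasses(24, seed = 41)
  res <- filterEffectExperiment(crops$wt, crops$mut,
                                kinds = c("none", "blur"),
                                policy = "clip",
                                K = 5L, innerK = 5L, nLambda = 20L,
                                seed = 5)
  expect_identical(res$kind, c("none", "blur"))
  expect_true(all(res$mean_auc >= 0 & res$mean_auc <= 1))
  # "none" equals the default pipeline on the same crops
  cfgF <- featureConfig()
  wtTab <- extractFeatureTable(crops$wt, cfgF, genotype = "WT")
  mutTab <- extractFeatureTable(crops$mut, cfgF, genotype = "MUT")
  ref <- suppressWarnings(wtReferenceStats(wtTab))
  ds <- buildDataset(
    removeOutliers(standardizeFeatures(wtTab, ref), policy = "clip")$table,
    removeOutliers(standardizeFeatures(mutTab, ref), policy = "clip")$table)
  direct <- nestedCV(ds, K = 5L, innerK = 5L, nLambda = 20L, seed = 5)
  expect_equal(res$mean_auc[1], direct$meanAuc)
  expect_error(filterEffectExperiment(crops$wt, crops$mut,
                                      kinds = "emboss"),
               "unknown filter")
})
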