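#' The logistic link
#'
#' `sigmoid(t) = 1 / (1 + exp(-t))`, mapping a linear predictor to the
#' posterior probability of the mutant class.
#'
#' @param t numeric.
#' @return values in (0, 1).
#' @export
#' @examples
#' sigmoid(log(3))  # 0.75
sigmoid <- function(t) 1 / (1 + exp(-t))

.asXY <- function(x, y = NULL) {
  if (is(x, "CellDataset")) return(list(X = x@X, y = x@y))
  X <- as.matrix(x)
  if (is.null(y)) stop("labels y are required when x is a matrix")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  list(X = X, y = as.integer(y))
}

.checkTwoClasses <- function(y) {
  if (length(unique(y)) < 2L)
    stop("both classes must be present")
}

#' Linear predictor and posterior probability of cells under a model
#'
#' @param model a [DiscriminativeModel-class].
#' @param x feature vector (length matching the model) or cells-by-features
#'   matrix.
#' @return list with `eta` (linear predictors `beta' x + alpha`) and
#'   `posterior` (`sigmoid(eta)`).
#' @export
linearPredictor <- function(model, x) {
  stopifnot(is(model, "DiscriminativeModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model@beta))
    stop("feature vector length ", ncol(x), " does not match the model's ",
         length(model@beta), " coefficients")
  eta <- as.numeric(.xbeta(as.matrix(x), unname(model@beta), model@alpha))
  list(eta = eta, posterior = sigmoid(eta))
}

#' Smallest penalty shrinking all coefficients to zero
#'
#' At the null model (intercept only, fitted probability `mean(y)`), the
#' coordinate-wise gradient of the average logistic deviance at feature j
#' is `x_j' (ybar - y) / n`; `lambdaMax` is the largest absolute gradient,
#' the smallest penalty at which the all-zero coefficient vector satisfies
#' the stationarity conditions.
#'
#' @param x design matrix or [CellDataset-class].
#' @param y binary labels (ignored when `x` is a dataset).
#' @return a single penalty value.
#' @export
lambdaMax <- function(x, y = NULL) {
  d <- .asXY(x, y)
  .checkTwoClasses(d$y)
  n <- nrow(d$X)
  max(abs(crossprod(d$X, d$y - mean(d$y)))) / n
}

#' Logarithmic penalty grid for the lasso path
#'
#' Log-spaced from [lambdaMax()] down `decades` decades, `nValues` values,
#' strictly decreasing. The first grid value yields the all-zero
#' coefficient vector by construction.
#'
#' @inheritParams lambdaMax
#' @param nValues grid length.
#' @param decades decades spanned below `lambdaMax`.
#' @return decreasing numeric vector of length `nValues`.
#' @export
lambdaGrid <- function(x, y = NULL, nValues = 100L, decades = 4) {
  lm0 <- lambdaMax(x, y)
  lm0 * 10^seq(0, -decades, length.out = nValues)
}

# fit the penalized path; thin wrapper around the compiled solver.
# devRatioMax < 1 enables the standard early stop once the fit explains
# that fraction of the null deviance (the overfit tail of the path).
.fitPath <- function(X, y, lambdas, tol = 1e-8, maxit = 100000L,
                     trace = FALSE, devRatioMax = 1.0, devFracMin = 0) {
  .cd_lasso_logistic(as.matrix(X), as.numeric(y), as.numeric(lambdas),
                     tol, as.integer(maxit), trace, devRatioMax,
                     devFracMin)
}

#' Fit an L1-regularized logistic discriminative model
#'
#' Minimizes the penalized average logistic deviance
#' `(1/n) sum_i [log(1 + exp(eta_i)) - y_i eta_i] + lambda ||beta||_1`
#' with unpenalized intercept by cyclic coordinate descent on successive
#' local quadratic approximations (proximal Newton / IRLS), with a
#' backtracking safeguard so the recorded objective trace is
#' non-increasing by construction. At `lambda >= lambdaMax` the fit is
#' the null model with `alpha = log(pbar / (1 - pbar))`.
#'
#' @param x design matrix (cells x features) or a [CellDataset-class].
#' @param y binary labels (ignored when `x` is a dataset).
#' @param lambda L1 penalty (>= 0).
#' @param tol convergence tolerance on the largest scaled squared
#'   coordinate step in a sweep.
#' @param maxit maximum coordinate-descent sweeps.
#' @param trace record the objective after every sweep.
#' @return list of class `FitResult` with `model`
#'   ([DiscriminativeModel-class]), `residuals` (`y - sigmoid(eta)`, in
#'   (-1, 1)) and `objectiveTrace`.
#' @export
#' @examples
#' tab <- generateFeatureTable(effectSpec(nFeatures = 5,
#'                                        shiftedIndices = 1L, delta = 2),
#'                             30, seed = 1)
#' ds <- buildDataset(tab[tab$genotype == "WT", ],
#'                    tab[tab$genotype == "MUT", ])
#' fit <- fitL1Logistic(ds, lambda = 0.05)
#' selectedFeatures(fit$model)
fitL1Logistic <- function(x, y = NULL, lambda, tol = 1e-9,
                          maxit = 100000L, trace = TRUE) {
  d <- .asXY(x, y)
  .checkTwoClasses(d$y)
  stopifnot(lambda >= 0)
  fit <- .fitPath(d$X, d$y, lambda, tol = tol, maxit = maxit,
                  trace = trace)
  tr <- if (trace) fit$trace[[1]] else numeric(0)
  if (!fit$converged[1]) {
    cond <- structure(
      class = c("bfprofilerConvergenceError", "error", "condition"),
      list(message = sprintf(
        "coordinate descent did not converge in %d sweeps (lambda=%g)",
        fit$iterations[1], lambda),
        call = sys.call(), trace = tr))
    stop(cond)
  }
  beta <- setNames(fit$beta[, 1], colnames(d$X))
  model <- new("DiscriminativeModel", alpha = fit$alpha[1], beta = beta,
               lambda = lambda,
               fitMeta = list(iterations = fit$iterations[1],
                              converged = TRUE,
                              objective = fit$objective[1],
                              schemaHash = .charHash(colnames(d$X))))
  eta <- as.numeric(.xbeta(d$X, unname(beta), fit$alpha[1]))
  structure(list(model = model, residuals = d$y - sigmoid(eta),
                 objectiveTrace = tr),
            class = "FitResult")
}

#' ROC curve and AUC of a score vector
#'
#' Step ROC over score thresholds; the reported AUC is the tie-corrected
#' Mann-Whitney statistic divided by `n1 * n0` (average ranks give tied
#' pairs half weight), which equals the trapezoidal area under the step
#' curve.
#'
#' @param scores numeric scores (higher = more mutant-like).
#' @param labels binary labels, 1 = positive (mutant).
#' @return list with `fpr`, `tpr` (step curve from (0,0) to (1,1)), `auc`
#'   and the Mann-Whitney statistic `U`.
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3), c(1, 0, 1))$auc  # 0.5
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  .checkTwoClasses(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)
  U <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  last <- c(which(diff(s) != 0), length(s))
  tpr <- c(0, cumsum(l == 1L)[last] / n1)
  fpr <- c(0, cumsum(l == 0L)[last] / n0)
  list(fpr = fpr, tpr = tpr, auc = U / (n1 * n0), U = U)
}

# stratified fold assignment; called inside a withSeed() block
.stratFolds <- function(y, K, stratified = TRUE) {
  fold <- integer(length(y))
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(K), length(y)))
  }
  fold
}

.meanDeviance <- function(etaMat, y) {
  p <- sigmoid(etaMat)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  colMeans(-(y * log(p) + (1 - y) * log1p(-p)))
}

#' Nested cross-validated evaluation of the discriminative model
#'
#' Stratified outer K-fold cross-validation estimates accuracy; on each
#' outer training split, an inner K-fold chooses the penalty lambda that
#' minimizes the mean validation deviance over a shared log grid
#' (lambda.min rule), the model is refit on the full outer training split
#' at the chosen penalty, and the held-out outer fold is scored. Reports
#' per-fold ROC curves and AUCs, their mean and SD, the chosen penalties
#' and the per-fold selected feature sets.
#'
#' @param x design matrix or [CellDataset-class].
#' @param y binary labels (ignored for a dataset).
#' @param K,innerK outer and inner fold counts (default tenfold both).
#' @param nLambda,decades penalty grid, see [lambdaGrid()].
#' @param seed integer seed for the fold assignments.
#' @param stratified stratify folds by class.
#' @param tol solver tolerance for the per-fold refits at the chosen
#'   penalty.
#' @param cvTol solver tolerance for the inner selection-only path fits;
#'   may be looser than `tol` since only validation deviances are needed.
#' @return list of class `NestedCVResult`: `foldCurves`, `foldAucs`,
#'   `meanAuc`, `sdAuc`, `lambdas`, `selected`, `folds`.
#' @export
nestedCV <- function(x, y = NULL, K = 10L, innerK = 10L, nLambda = 100L,
                     decades = 4, seed = 1L, stratified = TRUE,
                     tol = 1e-5, cvTol = tol) {
  d <- .asXY(x, y)
  .checkTwoClasses(d$y)
  if (min(table(d$y)) < 2L * K)
    stop("each class needs at least ", 2L * K, " cells for K=", K,
         " outer folds")
  withSeed(seed, {
    fold <- .stratFolds(d$y, K, stratified)
    foldAucs <- numeric(K)
    foldCurves <- vector("list", K)
    lambdas <- numeric(K)
    selected <- vector("list", K)
    for (k in seq_len(K)) {
      tr <- fold != k
      Xtr <- d$X[tr, , drop = FALSE]; ytr <- d$y[tr]
      grid <- lambdaGrid(Xtr, ytr, nValues = nLambda, decades = decades)
      inner <- .stratFolds(ytr, innerK, stratified)
      dev <- matrix(0, innerK, length(grid))
      for (j in seq_len(innerK)) {
        itr <- inner != j
        fit <- .fitPath(Xtr[itr, , drop = FALSE], ytr[itr], grid,
                        tol = cvTol, devRatioMax = 0.999,
                        devFracMin = 1e-5)
        eta <- Xtr[!itr, , drop = FALSE] %*% fit$beta
        eta <- sweep(eta, 2, fit$alpha, "+")
        dev[j, ] <- .meanDeviance(eta, ytr[!itr])
      }
      iStar <- which.min(colMeans(dev))
      lambdas[k] <- grid[iStar]
      refit <- .fitPath(Xtr, ytr, grid[seq_len(iStar)], tol = tol,
                        devRatioMax = 0.999, devFracMin = 1e-5)
      beta <- refit$beta[, iStar]
      alpha <- refit$alpha[iStar]
      selected[[k]] <- colnames(d$X)[beta != 0]
      etaTe <- as.numeric(d$X[!tr, , drop = FALSE] %*% beta + alpha)
      roc <- rocAuc(etaTe, d$y[!tr])
      foldAucs[k] <- roc$auc
      foldCurves[[k]] <- roc[c("fpr", "tpr")]
    }
    structure(list(foldCurves = foldCurves, foldAucs = foldAucs,
                   meanAuc = mean(foldAucs), sdAuc = sd(foldAucs),
                   lambdas = lambdas, selected = selected, folds = fold,
                   K = K),
              class = "NestedCVResult")
  })
}

#' @export
print.NestedCVResult <- function(x, ...) {
  cat("Nested ", x$K, "-fold CV: mean AUC = ", round(x$meanAuc, 4),
      " (SD ", round(x$sdAuc, 4), ")\n", sep = "")
  invisible(x)
}

#' Cross-validated penalty selection and full-data refit
#'
#' Selects lambda by stratified K-fold mean validation deviance on the
#' whole dataset and refits on all cells at the chosen penalty. This
#' full-data refit supplies the coefficient profile of a genotype for
#' profile clustering; nested CV ([nestedCV()]) remains the accuracy
#' estimate.
#'
#' @inheritParams nestedCV
#' @return a [DiscriminativeModel-class]; `fitMeta` records the grid, the
#'   CV deviances and the seed.
#' @export
fitModelCV <- function(x, y = NULL, K = 10L, nLambda = 100L, decades = 4,
                       seed = 1L, stratified = TRUE, tol = 1e-5,
                       cvTol = tol) {
  d <- .asXY(x, y)
  .checkTwoClasses(d$y)
  withSeed(seed, {
    grid <- lambdaGrid(d$X, d$y, nValues = nLambda, decades = decades)
    fold <- .stratFolds(d$y, K, stratified)
    dev <- matrix(0, K, length(grid))
    for (j in seq_len(K)) {
      tr <- fold != j
      fit <- .fitPath(d$X[tr, , drop = FALSE], d$y[tr], grid, tol = cvTol,
                      devRatioMax = 0.999, devFracMin = 1e-5)
      eta <- d$X[!tr, , drop = FALSE] %*% fit$beta
      eta <- sweep(eta, 2, fit$alpha, "+")
      dev[j, ] <- .meanDeviance(eta, d$y[!tr])
    }
    iStar <- which.min(colMeans(dev))
    refit <- .fitPath(d$X, d$y, grid[seq_len(iStar)], tol = tol,
                      devRatioMax = 0.999, devFracMin = 1e-5)
    new("DiscriminativeModel",
        alpha = refit$alpha[iStar],
        beta = setNames(refit$beta[, iStar], colnames(d$X)),
        lambda = grid[iStar],
        fitMeta = list(lambdaGrid = grid, cvDeviance = colMeans(dev),
                       seed = seed, iterations = refit$iterations[iStar],
                       converged = refit$converged[iStar],
                       schemaHash = .charHash(colnames(d$X))))
  })
}

#' One-sided Mann-Whitney U test between mutant and wild-type values
#'
#' Tie-corrected Mann-Whitney U. For combined sample sizes up to 12 the
#' p-value is computed by exact enumeration of all group assignments
#' (valid under ties); otherwise by the tie-corrected normal
#' approximation without continuity correction.
#'
#' @param mutantValues,wtValues numeric samples (both non-empty).
#' @param alternative `"greater"` (mutant values tend larger), `"less"`,
#'   or `"two.sided"`.
#' @return list with `U` (statistic for the mutant sample), `p`, and
#'   `method`.
#' @export
#' @examples
#' featureUTest(c(3, 4, 5), c(0, 1, 2), "greater")$p  # 1/20
featureUTest <- function(mutantValues, wtValues,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(mutantValues) == 0L || length(wtValues) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(mutantValues); n2 <- length(wtValues)
  pool <- c(mutantValues, wtValues)
  r <- rank(pool)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  eps <- 1e-9
  if (n1 + n2 <= 12L) {
    method <- "exact enumeration"
    combs <- combn(n1 + n2, n1)
    Uperm <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- switch(alternative,
      greater = mean(Uperm >= U - eps),
      less = mean(Uperm <= U + eps),
      two.sided = mean(abs(Uperm - mu) >= abs(U - mu) - eps))
  } else {
    method <- "normal approximation (tie corrected)"
    N <- n1 + n2
    ties <- table(pool)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sig2)
      p <- switch(alternative,
        greater = pnorm(z, lower.tail = FALSE),
        less = pnorm(z),
        two.sided = min(1, 2 * pnorm(-abs(z))))
    }
  }
  list(U = U, p = p, method = method)
}

#' AUC as a function of training-set size
#'
#' For each fraction, draws a stratified subsample without replacement
#' (seeded), runs [nestedCV()] on it, and reports the mean AUC with the SD
#' over repeats. Fractions too small to support K folds per class are
#' skipped with a warning. Each (fraction, repeat) uses the child seed
#' `childSeed(seed, counter)` with counters in row-major order; fraction
#' 1.0 with one repeat therefore reproduces
#' `nestedCV(..., seed = childSeed(seed, 1))`.
#'
#' @inheritParams nestedCV
#' @param fractions subsampling fractions in (0, 1].
#' @param repeats subsample draws per fraction.
#' @param ... further arguments passed to [nestedCV()].
#' @return `data.frame` with `fraction`, `n`, `mean_auc`, `sd_auc`.
#' @export
learningCurve <- function(x, y = NULL, fractions, repeats = 3L, seed = 1L,
                          K = 10L, ...) {
  d <- .asXY(x, y)
  stopifnot(all(fractions > 0), all(fractions <= 1), repeats >= 1)
  counter <- 0L
  rows <- list()
  for (f in fractions) {
    perClass <- floor(f * table(d$y))
    if (min(perClass) < 2L * K) {
      counter <- counter + repeats
      warning(sprintf(
        "fraction %.3g leaves fewer than %d cells in a class; skipped",
        f, 2L * K))
      next
    }
    aucs <- numeric(repeats)
    ntot <- NA_integer_
    for (r in seq_len(repeats)) {
      counter <- counter + 1L
      sr <- childSeed(seed, counter)
      idx <- if (f == 1) seq_along(d$y) else withSeed(sr, {
        sort(unlist(lapply(unique(d$y), function(cls) {
          ic <- which(d$y == cls)
          sample(ic, perClass[as.character(cls)])
        })))
      })
      ntot <- length(idx)
      res <- nestedCV(d$X[idx, , drop = FALSE], d$y[idx], K = K,
                      seed = sr, ...)
      aucs[r] <- res$meanAuc
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, n = ntot, mean_auc = mean(aucs),
      sd_auc = if (repeats > 1L) sd(aucs) else NA_real_)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Effect of image preprocessing filters on discrimination accuracy
#'
#' Applies each preprocessing kind to all crops before feature
#' extraction, runs the standard pipeline (wild-type standardization,
#' outlier handling, nested CV), and tabulates the mean AUC per kind.
#'
#' @param wtCrops,mutCrops lists of [CellCrop-class] objects for the two
#'   classes.
#' @param kinds subset of `"none"`, `"blur"`, `"edge_enhance"`,
#'   `"sharpen"`.
#' @param config a [featureConfig()].
#' @param cutoff,policy outlier handling, see [removeOutliers()].
#' @param ... further arguments passed to [nestedCV()] (e.g. `K`, `seed`).
#' @return `data.frame` with one row per kind: `kind`, `mean_auc`,
#'   `sd_auc`, `n`.
#' @export
filterEffectExperiment <- function(wtCrops, mutCrops, kinds = c(
                                     "none", "blur", "edge_enhance",
                                     "sharpen"),
                                   config = featureConfig(), cutoff = 3,
                                   policy = "drop_cell", ...) {
  ok <- c("none", names(.filterKernels()))
  if (!all(kinds %in% ok))
    stop("unknown filter kind: ",
         paste(setdiff(kinds, ok), collapse = ", "))
  rows <- list()
  for (kind in kinds) {
    fw <- if (kind == "none") wtCrops else
      lapply(wtCrops, applyFilter, kind = kind)
    fm <- if (kind == "none") mutCrops else
      lapply(mutCrops, applyFilter, kind = kind)
    wtTab <- extractFeatureTable(fw, config, genotype = "WT")
    mutTab <- extractFeatureTable(fm, config, genotype = "MUT")
    ref <- suppressWarnings(wtReferenceStats(wtTab))
    wtZ <- removeOutliers(standardizeFeatures(wtTab, ref), cutoff,
                          policy)$table
    mutZ <- removeOutliers(standardizeFeatures(mutTab, ref), cutoff,
                           policy)$table
    res <- nestedCV(buildDataset(wtZ, mutZ), ...)
    rows[[kind]] <- data.frame(kind = kind, mean_auc = res$meanAuc,
                               sd_auc = res$sdAuc,
                               n = nrow(wtZ) + nrow(mutZ))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write / read a discriminative model as JSON
#'
#' The JSON stores the intercept, penalty, the nonzero coefficients as a
#' sparse map, the full feature-name order and its hash, and optional
#' metadata; reading restores the dense coefficient vector with exact
#' zeros for unselected features.
#'
#' @param model a [DiscriminativeModel-class].
#' @param path file path.
#' @param genotype optional genotype label stored alongside.
#' @return `writeModelJSON` invisibly returns `path`; `readModelJSON`
#'   returns the model (with `fitMeta$genotype` set if stored).
#' @export
writeModelJSON <- function(model, path, genotype = NULL) {
  nz <- model@beta[model@beta != 0]
  obj <- list(genotype = genotype, alpha = model@alpha,
              lambda = model@lambda, beta = as.list(nz),
              feature_names = names(model@beta),
              schema_hash = model@fitMeta$schemaHash,
              seed = model@fitMeta$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  nm <- unlist(obj$feature_names)
  beta <- setNames(numeric(length(nm)), nm)
  if (length(obj$beta))
    beta[names(obj$beta)] <- unlist(obj$beta)
  new("DiscriminativeModel", alpha = obj$alpha, beta = beta,
      lambda = obj$lambda,
      fitMeta = list(genotype = obj$genotype,
                     schemaHash = obj$schema_hash, seed = obj$seed))
}
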