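## ---------------------------------------------------------------------------
## Cross-validated linear encoding and decoding models.
##
## Scoring discipline: each fold's model is fit on training rows only
## (features and responses z-scored with training-fold statistics), held-out
## rows are predicted, predictions are pooled across folds in stimulus
## order, and each target is scored once on the pooled predictions. Ordinary
## least squares ("glm") and ridge use closed-form solutions; lasso and
## penalized logistic regression use glmnet.
## ---------------------------------------------------------------------------

#' Build a cross-validation scheme
#'
#' @param n number of samples.
#' @param scheme "kfold" or "loo".
#' @param k number of folds (kfold only), 2 <= k <= n.
#' @param seed RNG seed for the random fold assignment; the same
#'   (n, scheme, k, seed) always yields identical folds.
#' @return a \linkS4class{CVScheme}.
#' @export
makeFolds <- function(n, scheme = c("kfold", "loo"), k = 10L, seed = 0L) {
  scheme <- match.arg(scheme)
  if (scheme == "loo") {
    folds <- as.list(seq_len(n))
    k <- n
  } else {
    if (k < 2 || k > n) usageError(sprintf("k must be in [2, %d]", n))
    perm <- withSeed(seed, sample.int(n))
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    folds <- split(perm, rep(seq_len(k), times = sizes))
    names(folds) <- NULL
  }
  new("CVScheme", kind = scheme, k = as.integer(k), seed = as.integer(seed),
      n = as.integer(n), folds = folds)
}

## Closed-form fits on standardized data. X: n x p, Y: n x q (both already
## z-scored per training fold). Returns p x q coefficient matrix.
fitLinearFamily <- function(X, Y, family, penalty) {
  switch(family,
    glm = {
      B <- qr.coef(qr(cbind(1, X)), Y)[-1, , drop = FALSE]
      B[is.na(B)] <- 0   # aliased (constant/collinear) features drop out
      B
    },
    ridge = {
      p <- ncol(X)
      solve(crossprod(X) + diag(penalty, p), crossprod(X, Y))
    },
    lasso = {
      B <- matrix(0, ncol(X), ncol(Y))
      for (j in seq_len(ncol(Y))) {
        f <- glmnet::glmnet(X, Y[, j], alpha = 1, lambda = penalty,
                            standardize = FALSE, intercept = TRUE)
        B[, j] <- as.numeric(f$beta)
      }
      B
    },
    usageError(sprintf("unknown family '%s'", family)))
}

defaultPenalty <- function(family) switch(family, ridge = 1.0, lasso = 0.01, 0)

resolveXY <- function(X, Y) {
  if (is(Y, "ResponseMatrix")) {
    yv <- Y@values; sid <- Y@siteIds; stim <- Y@stimIds
  } else {
    Y <- as.matrix(Y)
    yv <- Y; sid <- colnames(Y) %||% sprintf("site%03d", seq_len(ncol(Y)))
    stim <- rownames(Y) %||% sprintf("stim%03d", seq_len(nrow(Y)))
  }
  X <- as.matrix(X)
  if (!is.null(rownames(X)) && !identical(rownames(X), stim))
    alignmentError("stimulus IDs of X do not match Y (no silent reordering)")
  if (nrow(X) != nrow(yv))
    alignmentError(sprintf("X has %d rows but Y has %d", nrow(X), nrow(yv)))
  if (anyNA(X)) usageError("X must not contain NaN")
  list(X = X, yv = yv, siteIds = sid, stimIds = stim)
}

## Sites excluded from fitting: any NaN, or zero variance.
excludeSites <- function(yv, sid) {
  bad <- vapply(seq_len(ncol(yv)), function(j) {
    v <- yv[, j]
    anyNA(v) || stats::sd(v) == 0
  }, logical(1))
  list(keep = which(!bad), excluded = sid[bad])
}

#' Fit a cross-validated univariate encoding model
#'
#' For every measurement site independently, fits a linear model from the
#' feature matrix to the site's responses on the training folds, predicts
#' the held-out folds, pools the held-out predictions and scores each site
#' with the Pearson correlation between measured and predicted responses
#' (plus explained variance). Reported weights come from a final whole-data
#' fit. Sites containing NaN or with constant response are excluded and
#' listed.
#'
#' @param X feature matrix (n_stim x n_feat); no NaN allowed.
#' @param Y a \linkS4class{ResponseMatrix} (or plain matrix) aligned to X
#'   by stimulus order.
#' @param family "glm" (ordinary least squares), "ridge" or "lasso".
#' @param cv a \linkS4class{CVScheme}.
#' @param penalty ridge/lasso penalty (defaults: ridge 1.0, lasso 0.01).
#' @param standardize z-score features and responses with training-fold
#'   statistics (default TRUE).
#' @return an \linkS4class{EncodingResult}.
#' @export
fitUnivariateEncoding <- function(X, Y, family = c("glm", "ridge", "lasso"),
                                  cv, penalty = NULL, standardize = TRUE) {
  family <- match.arg(family)
  penalty <- penalty %||% defaultPenalty(family)
  d <- resolveXY(X, Y)
  ex <- excludeSites(d$yv, d$siteIds)
  yv <- d$yv[, ex$keep, drop = FALSE]
  pooled <- matrix(NA_real_, nrow(d$X), length(ex$keep))
  for (fold in cv@folds) {
    tr <- setdiff(seq_len(nrow(d$X)), fold)
    xs <- if (standardize) colStats(d$X[tr, , drop = FALSE])
          else list(mean = rep(0, ncol(d$X)), sd = rep(1, ncol(d$X)))
    ys <- if (standardize) colStats(yv[tr, , drop = FALSE])
          else list(mean = rep(0, ncol(yv)), sd = rep(1, ncol(yv)))
    Xtr <- applyStats(d$X[tr, , drop = FALSE], xs)
    Ytr <- applyStats(yv[tr, , drop = FALSE], ys)
    B <- fitLinearFamily(Xtr, Ytr, family, penalty)
    Xte <- applyStats(d$X[fold, , drop = FALSE], xs)
    pred <- Xte %*% B
    pooled[fold, ] <- sweep(sweep(pred, 2, ys$sd, "*"), 2, ys$mean, "+")
  }
  scores <- data.frame(
    site_id = d$siteIds[ex$keep],
    pearson_r = vapply(seq_len(ncol(yv)), function(j)
      scorePredictions(yv[, j], pooled[, j], "pearson_r"), numeric(1)),
    explained_variance = vapply(seq_len(ncol(yv)), function(j)
      scorePredictions(yv[, j], pooled[, j], "explained_variance"), numeric(1)),
    stringsAsFactors = FALSE)
  ## final whole-data fit, mapped back to the raw feature/response scale
  xs <- if (standardize) colStats(d$X) else list(mean = rep(0, ncol(d$X)),
                                                 sd = rep(1, ncol(d$X)))
  ys <- if (standardize) colStats(yv) else list(mean = rep(0, ncol(yv)),
                                                sd = rep(1, ncol(yv)))
  Bz <- fitLinearFamily(applyStats(d$X, xs), applyStats(yv, ys), family, penalty)
  W <- Bz * outer(1 / xs$sd, ys$sd)
  intercepts <- ys$mean - as.numeric(crossprod(W, xs$mean))
  colnames(W) <- d$siteIds[ex$keep]
  colnames(pooled) <- d$siteIds[ex$keep]
  new("EncodingResult", family = family, scores = scores, weights = W,
      intercepts = intercepts, pooledPredictions = pooled,
      excludedSites = d$siteIds[setdiff(seq_along(d$siteIds), ex$keep)],
      cv = cv,
      metadata = list(penalty = penalty, standardize = standardize,
                      score_metric = "pearson_r"))
}

#' Fit a cross-validated multivariate PLS encoding model
#'
#' Fits one partial-least-squares regression from the feature matrix to all
#' sites jointly (maximizing the covariance of the transformed variables),
#' predicting every site from the shared latent components. Held-out
#' predictions are pooled and scored per site exactly as in the univariate
#' case.
#'
#' @param X feature matrix (n_stim x n_feat).
#' @param Y a \linkS4class{ResponseMatrix} or matrix.
#' @param nComponents number of latent components (default
#'   min(10, n_feat, n_train - 1)).
#' @param cv a \linkS4class{CVScheme}.
#' @param standardize z-score with training-fold statistics (default TRUE).
#' @return an \linkS4class{EncodingResult} with family "pls".
#' @export
fitMultivariatePLSEncoding <- function(X, Y, nComponents = NULL, cv,
                                       standardize = TRUE) {
  d <- resolveXY(X, Y)
  minTrain <- min(vapply(cv@folds, function(f) nrow(d$X) - length(f),
                         integer(1)))
  lim <- min(ncol(d$X), minTrain - 1L)
  nComponents <- nComponents %||% min(10L, lim)
  if (nComponents < 1 || nComponents > lim)
    usageError(sprintf("nComponents must be in [1, %d]", lim))
  ex <- excludeSites(d$yv, d$siteIds)
  yv <- d$yv[, ex$keep, drop = FALSE]
  cn <- sprintf("f%d", seq_len(ncol(d$X)))
  sn <- sprintf("s%d", seq_len(ncol(yv)))
  pooled <- matrix(NA_real_, nrow(d$X), ncol(yv))
  for (fold in cv@folds) {
    tr <- setdiff(seq_len(nrow(d$X)), fold)
    xs <- if (standardize) colStats(d$X[tr, , drop = FALSE])
          else list(mean = rep(0, ncol(d$X)), sd = rep(1, ncol(d$X)))
    ys <- if (standardize) colStats(yv[tr, , drop = FALSE])
          else list(mean = rep(0, ncol(yv)), sd = rep(1, ncol(yv)))
    Xtr <- applyStats(d$X[tr, , drop = FALSE], xs); colnames(Xtr) <- cn
    Ytr <- applyStats(yv[tr, , drop = FALSE], ys); colnames(Ytr) <- sn
    fit <- mixOmics::pls(Xtr, Ytr, ncomp = nComponents, mode = "regression",
                         scale = FALSE)
    Xte <- applyStats(d$X[fold, , drop = FALSE], xs); colnames(Xte) <- cn
    pred <- predict(fit, newdata = Xte)$predict[, , nComponents, drop = FALSE]
    pred <- matrix(pred, nrow = length(fold))
    pooled[fold, ] <- sweep(sweep(pred, 2, ys$sd, "*"), 2, ys$mean, "+")
  }
  scores <- data.frame(
    site_id = d$siteIds[ex$keep],
    pearson_r = vapply(seq_len(ncol(yv)), function(j)
      scorePredictions(yv[, j], pooled[, j], "pearson_r"), numeric(1)),
    explained_variance = vapply(seq_len(ncol(yv)), function(j)
      scorePredictions(yv[, j], pooled[, j], "explained_variance"), numeric(1)),
    stringsAsFactors = FALSE)
  ## final whole-data fit for weights (regression coefficients per site)
  xs <- colStats(d$X); ys <- colStats(yv)
  Xa <- applyStats(d$X, xs); colnames(Xa) <- cn
  Ya <- applyStats(yv, ys); colnames(Ya) <- sn
  fit <- mixOmics::pls(Xa, Ya, ncomp = nComponents, mode = "regression",
                       scale = FALSE)
  Bz <- plsCoefficients(fit, nComponents)
  W <- Bz * outer(1 / xs$sd, ys$sd)
  intercepts <- ys$mean - as.numeric(crossprod(W, xs$mean))
  colnames(W) <- d$siteIds[ex$keep]
  colnames(pooled) <- d$siteIds[ex$keep]
  new("EncodingResult", family = "pls", scores = scores, weights = W,
      intercepts = intercepts, pooledPredictions = pooled,
      excludedSites = d$siteIds[setdiff(seq_along(d$siteIds), ex$keep)],
      cv = cv,
      metadata = list(n_components = nComponents, standardize = standardize,
                      score_metric = "pearson_r"))
}

## Regression coefficient matrix (p x q) implied by a fitted mixOmics pls
## model at a given number of components. The prediction map is affine, so
## the coefficients are recovered exactly by predicting the identity basis.
plsCoefficients <- function(fit, ncomp) {
  p <- ncol(fit$X)
  basis <- rbind(matrix(0, 1, p), diag(p))
  colnames(basis) <- colnames(fit$X)
  pr <- predict(fit, newdata = basis)$predict[, , ncomp, drop = FALSE]
  pr <- matrix(pr, nrow = p + 1)
  sweep(pr[-1, , drop = FALSE], 2, pr[1, ], "-")
}

#' Fit a cross-validated decoding model
#'
#' Predicts labels (classification, family "logistic") or a continuous
#' target (regression families) from multivariate responses -- measured
#' sites or network activations. Held-out predictions are pooled; the
#' pooled score is accuracy (fraction of correct predictions) for
#' classification and Pearson r for regression, with per-fold scores
#' retained.
#'
#' @param X a \linkS4class{ResponseMatrix} or numeric matrix
#'   (n_stim x n_predictors). Sites containing NaN are excluded.
#' @param y labels (2+ classes) or numeric target, length = rows of X.
#' @param family "logistic", "glm", "ridge" or "lasso".
#' @param cv a \linkS4class{CVScheme}.
#' @param penalty regularization strength. For "logistic" this is the
#'   inverse-regularization C of the L2 penalty (default 1.0; the glmnet
#'   lambda used is 1/(n C)).
#' @param standardize z-score predictors with training-fold statistics.
#' @return a \linkS4class{DecodingResult}.
#' @export
fitDecoding <- function(X, y, family = c("logistic", "glm", "ridge", "lasso"),
                        cv, penalty = NULL, standardize = TRUE) {
  family <- match.arg(family)
  if (is(X, "ResponseMatrix")) {
    ex <- excludeSites(X@values, X@siteIds)
    X <- X@values[, ex$keep, drop = FALSE]
  }
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    alignmentError("y length must equal the number of rows of X")
  classify <- family == "logistic"
  if (classify) {
    y <- as.character(y)
    lev <- sort(unique(y))
    if (length(lev) < 2)
      usageError("classification requires at least 2 classes present")
    if (length(lev) > 2)
      usageError("only binary classification is supported")
    penalty <- penalty %||% 1.0
  } else {
    y <- as.numeric(y)
    penalty <- penalty %||% defaultPenalty(family)
  }
  pooled <- if (classify) character(nrow(X)) else numeric(nrow(X))
  perFold <- numeric(length(cv@folds))
  for (fi in seq_along(cv@folds)) {
    fold <- cv@folds[[fi]]
    tr <- setdiff(seq_len(nrow(X)), fold)
    xs <- if (standardize) colStats(X[tr, , drop = FALSE])
          else list(mean = rep(0, ncol(X)), sd = rep(1, ncol(X)))
    Xtr <- applyStats(X[tr, , drop = FALSE], xs)
    Xte <- applyStats(X[fold, , drop = FALSE], xs)
    if (classify) {
      lam <- 1 / (length(tr) * penalty)
      f <- glmnet::glmnet(Xtr, factor(y[tr], levels = lev),
                          family = "binomial", alpha = 0, lambda = lam,
                          standardize = FALSE)
      pred <- as.character(predict(f, Xte, type = "class"))
      pooled[fold] <- pred
      perFold[fi] <- mean(pred == y[fold])
    } else {
      ys <- if (standardize) colStats(matrix(y[tr]))
            else list(mean = 0, sd = 1)
      B <- fitLinearFamily(Xtr, matrix((y[tr] - ys$mean) / ys$sd), family,
                           penalty)
      pred <- as.numeric(Xte %*% B) * ys$sd + ys$mean
      pooled[fold] <- pred
      perFold[fi] <- if (length(fold) >= 3 && stats::sd(y[fold]) > 0 &&
                         stats::sd(pred) > 0)
        stats::cor(y[fold], pred) else NA_real_
    }
  }
  if (classify) {
    score <- mean(pooled == y)
    metric <- "accuracy"
    xsAll <- if (standardize) colStats(X) else NULL
    Xa <- if (standardize) applyStats(X, xsAll) else X
    f <- glmnet::glmnet(Xa, factor(y, levels = lev), family = "binomial",
                        alpha = 0, lambda = 1 / (nrow(X) * penalty),
                        standardize = FALSE)
    w <- as.numeric(f$beta)
  } else {
    score <- scorePredictions(y, pooled, "pearson_r")
    metric <- "pearson_r"
    enc <- fitLinearFamily(scale(X), matrix(scale(y)), family, penalty)
    w <- as.numeric(enc)
  }
  new("DecodingResult", family = family, score = score, scoreMetric = metric,
      perFoldScores = perFold, pooledPredictions = pooled, weights = w,
      cv = cv, metadata = list(penalty = penalty, standardize = standardize))
}

#' Score predictions against ground truth
#'
#' @param yTrue,yPred equal-length vectors (length >= 2; >= 3 for
#'   pearson_r).
#' @param metric "accuracy", "pearson_r" or "explained_variance".
#' @return the score. \code{pearson_r} is undefined when either vector is
#'   constant and is returned as NA (flagged, never silently 0).
#' @export
scorePredictions <- function(yTrue, yPred,
                             metric = c("accuracy", "pearson_r",
                                        "explained_variance")) {
  metric <- match.arg(metric)
  if (length(yTrue) != length(yPred))
    usageError("yTrue and yPred must have equal length")
  if (length(yTrue) < 2) usageError("need at least 2 observations")
  switch(metric,
    accuracy = mean(yTrue == yPred),
    pearson_r = {
      if (length(yTrue) < 3) usageError("pearson_r needs >= 3 observations")
      if (stats::sd(yTrue) == 0 || stats::sd(yPred) == 0) return(NA_real_)
      stats::cor(yTrue, yPred)
    },
    explained_variance = 1 - stats::var(yTrue - yPred) / stats::var(yTrue))
}

#' Permutation test of a cross-validated score
#'
#' Computes the observed score with the supplied procedure, then rebuilds
#' the null distribution by refitting on \code{nPerm} seeded permutations
#' of the targets. The p-value uses the add-one convention
#' (1 + #\{null >= observed\}) / (1 + nPerm) and is therefore always in
#' (0, 1].
#'
#' @param fitScore function(X, y, cv) returning a scalar score.
#' @param X predictor matrix (passed through unchanged).
#' @param y targets to permute.
#' @param cv a \linkS4class{CVScheme}, passed to \code{fitScore}.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param alternative "greater" (default), "less" or "two.sided".
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(fitScore, X, y, cv, nPerm = 1000L, seed = 0L,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (nPerm < 1) usageError("nPerm must be >= 1")
  observed <- fitScore(X, y, cv)
  nulls <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      yp <- if (is.null(dim(y))) sample(y) else y[sample(nrow(y)), , drop = FALSE]
      fitScore(X, yp, cv)
    }, numeric(1))
  })
  hits <- switch(alternative,
    greater = sum(nulls >= observed),
    less = sum(nulls <= observed),
    two.sided = sum(abs(nulls - mean(nulls)) >= abs(observed - mean(nulls))))
  new("PermutationResult", observed = observed, nullSamples = nulls,
      pValue = (1 + hits) / (1 + nPerm), seed = as.integer(seed))
}
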