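test_that("fold construction satisfies the CV invariants", {
  cv <- makeFolds(10, "kfold", k = 5, seed = 1)
  expect_length(cv@folds, 5)
  expect_true(all(lengths(cv@folds) == 2))
  expect_identical(sort(unlist(cv@folds)), 1:10)

  loo <- makeFolds(4, "loo")
  expect_length(loo@folds, 4)
  expect_true(all(lengths(loo@folds) == 1))

  ## determinism and seed sensitivity
  expect_identical(makeFolds(100, "kfold", k = 10, seed = 3)@folds,
                   makeFolds(100, "kfold", k = 10, seed = 3)@folds)
  expect_false(identical(makeFolds(100, "kfold", k = 10, seed = 3)@folds,
                         makeFolds(100, "kfold", k = 10, seed = 4)@folds))
  ## uneven n: sizes differ by at most one
  cv7 <- makeFolds(17, "kfold", k = 5, seed = 2)
  expect_lte(diff(range(lengths(cv7@folds))), 1)
  expect_error(makeFolds(5, "kfold", k = 6), class = "dnnmapr_usage_error")
  expect_error(makeFolds(5, "kfold", k = 1), class = "dnnmapr_usage_error")
})

test_that("univariate encoding recovers a noiseless linear linkage exactly", {
  prob <- linkageProblem(n = 60, p = 3, q = 2, seed = 1)
  cv <- makeFolds(60, "kfold", k = 10, seed = 1)
  enc <- fitUnivariateEncoding(prob$X, prob$Y, "glm", cv)
  expect_true(all(encodingScores(enc)$pearson_r >= 0.999))
  expect_lt(max(abs(enc@weights - prob$W)), 1e-6)
  ## explained variance of a perfect prediction is 1
  expect_true(all(encodingScores(enc)$explained_variance > 0.999))
})

test_that("encoding on independent noise stays within the null bound", {
  set.seed(2)
  X <- matrix(rnorm(200 * 3), 200, 3)
  Y <- ResponseMatrix(matrix(rnorm(200 * 20), 200, 20))
  enc <- fitUnivariateEncoding(X, Y, "glm", makeFolds(200, "kfold", 10, 2))
  expect_lt(mean(abs(encodingScores(enc)$pearson_r)), 0.15)  # ~2/sqrt(n)
})

test_that("degenerate and misaligned encoding inputs are rejected or excluded", {
  prob <- linkageProblem(seed = 3)
  cv <- makeFolds(60, "kfold", k = 5, seed = 1)
  ## constant site excluded, no score emitted
  Yc <- ResponseMatrix(cbind(prob$Y@values[, 1], 7),
                       siteIds = c("good", "flat"))
  enc <- fitUnivariateEncoding(prob$X, Yc, "glm", cv)
  expect_identical(enc@excludedSites, "flat")
  expect_identical(encodingScores(enc)$site_id, "good")
  ## NaN site excluded and listed
  Yn <- prob$Y@values; Yn[4, 2] <- NaN
  encn <- fitUnivariateEncoding(prob$X, ResponseMatrix(Yn), "glm", cv)
  expect_length(encn@excludedSites, 1)
  ## misaligned stimulus ids
  Xn <- prob$X; rownames(Xn) <- rev(stimIds(prob$Y))
  expect_error(fitUnivariateEncoding(Xn, prob$Y, "glm", cv),
               class = "dnnmapr_alignment_error")
  ## ridge and lasso run on the same problem and stay near-perfect
  for (fam in c("ridge", "lasso")) {
    e <- fitUnivariateEncoding(prob$X, prob$Y, fam, cv, penalty = 1e-4)
    expect_true(all(encodingScores(e)$pearson_r > 0.99), info = fam)
  }
})

test_that("PLS encoding recovers a rank-1 linkage and the univariate weight", {
  ## single-latent design: X varies along one direction only, so one PLS
  ## component provably carries the whole linkage
  set.seed(4)
  n <- 60
  X <- outer(rnorm(n), c(1, -0.5, 2))
  w <- c(1, -2, 0.5); a <- rnorm(5)
  Y <- ResponseMatrix((X %*% w) %*% t(a))
  cv <- makeFolds(n, "kfold", k = 10, seed = 1)
  pls <- fitMultivariatePLSEncoding(X, Y, nComponents = 1, cv = cv)
  expect_true(all(encodingScores(pls)$pearson_r >= 0.999))
  expect_error(fitMultivariatePLSEncoding(X, Y, nComponents = 0, cv = cv),
               class = "dnnmapr_usage_error")

  ## first PLS X-weight is proportional to X'y for univariate y
  y <- rnorm(n)
  X <- matrix(rnorm(n * 3), n, 3)
  Xc <- scale(X, scale = FALSE); colnames(Xc) <- paste0("f", 1:3)
  fit <- mixOmics::pls(Xc, matrix(y - mean(y)), ncomp = 1,
                       mode = "regression", scale = FALSE)
  wx <- fit$loadings$X[, 1]
  ref <- crossprod(Xc, y - mean(y))
  cosine <- abs(sum(wx * ref)) / sqrt(sum(wx^2) * sum(ref^2))
  expect_gte(cosine, 0.999)
})

test_that("decoding is perfect on separable classes and chance on shuffled labels", {
  dd <- makeCategoryDataset(100, "linear_margin", seed = 5)
  dec <- fitDecoding(dd$features, dd$labels, "logistic",
                     makeFolds(100, "kfold", k = 10, seed = 3))
  expect_identical(dec@score, 1.0)
  expect_identical(dec@scoreMetric, "accuracy")
  expect_length(dec@perFoldScores, 10)

  d4 <- makeCategoryDataset(400, "linear_margin", seed = 6)
  ysh <- withr::with_seed(7, sample(d4$labels))
  dec0 <- fitDecoding(d4$features, ysh, "logistic",
                      makeFolds(400, "kfold", k = 10, seed = 3))
  expect_lt(abs(dec0@score - 0.5), 0.075)   # 3 * sqrt(0.25/400)

  ## continuous noiseless target through the glm family
  set.seed(8)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y <- as.numeric(X %*% c(1, 2, 3))
  decc <- fitDecoding(X, y, "glm", makeFolds(200, "kfold", k = 10, seed = 4))
  expect_gte(decc@score, 0.999)
  expect_identical(decc@scoreMetric, "pearson_r")

  expect_error(fitDecoding(dd$features, rep("a", 100), "logistic",
                           makeFolds(100, "kfold", k = 5, seed = 1)),
               class = "dnnmapr_usage_error")
})

test_that("decoding excludes NaN sites from a ResponseMatrix", {
  dd <- makeCategoryDataset(60, "linear_margin", seed = 9)
  vals <- cbind(dd$features, NaN)
  rm <- ResponseMatrix(vals, siteIds = c("s1", "s2", "bad"))
  dec <- fitDecoding(rm, dd$labels, "logistic",
                     makeFolds(60, "kfold", k = 5, seed = 1))
  expect_identical(dec@score, 1.0)
  expect_length(dec@weights, 2)      # NaN site dropped before fitting
})

test_that("prediction scoring matches hand-computed values and flags degeneracy", {
  expect_equal(scorePredictions(c(1, 0, 1), c(1, 1, 1), "accuracy"), 2 / 3)
  v <- c(0.3, -1, 2, 5)
  expect_equal(scorePredictions(v, v, "pearson_r"), 1.0)
  expect_equal(scorePredictions(v, v, "explained_variance"), 1.0)
  expect_true(is.na(scorePredictions(c(1, 2, 3), c(2, 2, 2), "pearson_r")))
  expect_error(scorePredictions(1:3, 1:4, "accuracy"),
               class = "dnnmapr_usage_error")
})

test_that("permutation p-values follow the add-one convention", {
  cv <- makeFolds(20, "kfold", k = 4, seed = 1)
  ## observed strictly above all 99 nulls -> p = 1/100
  set.seed(10)
  X <- matrix(rnorm(20), 20, 1)
  y <- as.numeric(X) + rnorm(20, sd = 0.01)
  strong <- permutationTest(function(X, y, cv) cor(X[, 1], y),
                            X, y, cv, nPerm = 99, seed = 2)
  expect_identical(strong@pValue, 0.01)
  expect_length(strong@nullSamples, 99)
  ## statistic constant in y -> p = 1
  flat <- permutationTest(function(X, y, cv) 0, X, y, cv, nPerm = 99, seed = 2)
  expect_identical(flat@pValue, 1.0)
  ## nPerm = 1 -> p in {0.5, 1}
  one <- permutationTest(function(X, y, cv) cor(X[, 1], y), X, y, cv,
                         nPerm = 1, seed = 3)
  expect_true(one@pValue %in% c(0.5, 1.0))
  expect_gt(one@pValue, 0)
})

test_that("held-out responses never influence a fold's fitted model", {
  prob <- linkageProblem(n = 30, p = 2, q = 1, seed = 11)
  cv <- makeFolds(30, "kfold", k = 5, seed = 2)
  fold1 <- cv@folds[[1]]
  enc1 <- fitUnivariateEncoding(prob$X, prob$Y, "glm", cv)
  ## perturb responses of held-out rows of fold 1 only
  Y2 <- prob$Y@values
  Y2[fold1, ] <- Y2[fold1, ] + 100
  enc2 <- fitUnivariateEncoding(prob$X, ResponseMatrix(Y2), "glm", cv)
  expect_equal(enc1@pooledPredictions[fold1, ],
               enc2@pooledPredictions[fold1, ], tolerance = 1e-12)
})

test_that("encoding and decoding a single noiseless site are symmetric", {
  set.seed(12)
  x <- matrix(rnorm(40), 40, 1)
  y <- 2 * x[, 1] + 1
  cv <- makeFolds(40, "kfold", k = 5, seed = 3)
  enc <- fitUnivariateEncoding(x, ResponseMatrix(matrix(y)), "glm", cv)
  dec <- fitDecoding(matrix(y), x[, 1], "glm", cv)
  expect_equal(abs(encodingScores(enc)$pearson_r), abs(dec@score),
               tolerance = 1e-9)
})
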