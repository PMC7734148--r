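test_that("toy networks are reproducible and shape-consistent", {
  m1 <- twoConvNet(seed = 21)
  m2 <- twoConvNet(seed = 21)
  expect_identical(m1@layers, m2@layers)
  expect_false(identical(m1@layers, twoConvNet(seed = 22)@layers))

  ## hand-computed convolution arithmetic on a 16x16 input
  m <- makeToyNetwork(
    list(list(kind = "conv", out = 4, kernel = 5), list(kind = "relu"),
         list(kind = "pool", size = 2),
         list(kind = "conv", out = 8, kernel = 3), list(kind = "relu"),
         list(kind = "linear", out = 10)),
    inputShape = c(1L, 16L, 16L), seed = 1)
  shp <- layerShapes(m)
  expect_identical(shp$conv1, c(4L, 12L, 12L))   # 16 - 5 + 1
  expect_identical(shp$pool1, c(4L, 6L, 6L))
  expect_identical(shp$conv2, c(8L, 4L, 4L))
  expect_identical(shp$fc1, 10L)

  ## identity scheme: forward is the identity map
  mi <- makeToyNetwork(list(list(kind = "linear", out = 6)), 6L,
                       weightScheme = "identity")
  x <- matrix(rnorm(18), 3, 6)
  expect_identical(networkForward(mi, x)$output, x)
})

test_that("synthetic stimuli carry the promised structure and attributes", {
  s1 <- makeSyntheticStimuli(10, c(1, 8, 8), seed = 23, kind = "noise")
  s2 <- makeSyntheticStimuli(10, c(1, 8, 8), seed = 23, kind = "noise")
  expect_identical(s1$batch, s2$batch)
  expect_identical(stimIds(s1$table), sprintf("stim%03d", 1:10))

  g <- makeSyntheticStimuli(6, c(1, 12, 12), seed = 24, kind = "gabor_bank")
  ori <- g$table@data$orientation_deg
  expect_length(ori, 6)
  expect_true(all(ori >= 0 & ori < 180))

  b <- makeSyntheticStimuli(12, c(1, 10, 10), seed = 25, kind = "blob")
  for (i in 1:12) {
    img <- b$batch[i, 1, , ]
    peak <- which(img == max(img), arr.ind = TRUE)[1, ]
    expect_identical(unname(peak) - 1L,
                     c(b$table@data$blob_row[i], b$table@data$blob_col[i]))
  }
})

test_that("linked responses have recoverable ground truth across seeds", {
  m <- twoConvNet(seed = 26)
  x <- randBatch(60, c(1, 10, 10), seed = 27)
  ## fc1 features are full-rank (no rectification), so the linkage weights
  ## are identifiable and must be recovered exactly in the noiseless case
  store <- extractActivations(m, x, MaskSpec(fc1 = "all"))
  cv <- makeFolds(60, "kfold", k = 5, seed = 1)
  ## noiseless linkage: weight recovery < 1e-6 for every seed in a sweep
  for (seed in 1:10) {
    linked <- makeLinkedResponses(store, "fc1", nSites = 2, noiseSd = 0,
                                  seed = seed)
    feats <- summarizeActivation(store, "mean")$fc1
    enc <- fitUnivariateEncoding(feats, linked$responses, "glm", cv)
    expect_lt(max(abs(enc@weights - linked$truth@weights)), 1e-6)
    expect_true(all(encodingScores(enc)$pearson_r >= 0.999))
  }
  ## determinism
  a <- makeLinkedResponses(store, "fc1", nSites = 3, noiseSd = 0.5, seed = 4)
  b <- makeLinkedResponses(store, "fc1", nSites = 3, noiseSd = 0.5, seed = 4)
  expect_identical(a$responses@values, b$responses@values)
})

test_that("overwhelming noise drives encoding accuracy to the null bound", {
  m <- twoConvNet(seed = 28)
  x <- randBatch(200, c(1, 10, 10), seed = 29)
  store <- extractActivations(m, x, MaskSpec(conv2 = "all"))
  linked <- makeLinkedResponses(store, "conv2", nSites = 4, noiseSd = 1e6,
                                seed = 5)
  feats <- summarizeActivation(store, "mean")$conv2
  enc <- fitUnivariateEncoding(feats, linked$responses, "glm",
                               makeFolds(200, "kfold", k = 10, seed = 2))
  expect_lt(mean(abs(encodingScores(enc)$pearson_r)), 0.15)
})

test_that("category datasets obey their separability rules and balance", {
  dd <- makeCategoryDataset(100, "linear_margin", seed = 30)
  expect_lte(abs(sum(dd$labels == "a") - sum(dd$labels == "b")), 1)
  ## margin holds by construction: classes split by sign of feature 1
  expect_true(all(dd$features[dd$labels == "a", 1] >= 3))
  expect_true(all(dd$features[dd$labels == "b", 1] <= -3))

  dx <- makeCategoryDataset(401, "xor", seed = 31)
  expect_lte(abs(sum(dx$labels == "a") - sum(dx$labels == "b")), 1)
  ## xor rule: label matches the sign product
  expect_true(all((dx$features[, 1] * dx$features[, 2] > 0) ==
                    (dx$labels == "a")))
  ## and a linear decoder stays at chance
  dec <- fitDecoding(dx$features[1:400, ], dx$labels[1:400], "logistic",
                     makeFolds(400, "kfold", k = 10, seed = 3))
  expect_lte(abs(dec@score - 0.5), 0.075 + 1e-12)
})

test_that("fixture generation leaves the global RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(makeSyntheticStimuli(5, c(1, 6, 6), seed = 1))
  invisible(makeCategoryDataset(10, "xor", seed = 2))
  invisible(makeToyNetwork(list(list(kind = "linear", out = 2)), 2L, seed = 3))
  expect_identical(.Random.seed, before)
})
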