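test_that("extraction matches hand-computed activations on analytic nets", {
  ## identity linear layer: activations equal inputs exactly
  mi <- makeToyNetwork(list(list(kind = "linear", out = 4)), 4L,
                       weightScheme = "identity")
  xi <- matrix(rnorm(12), 3, 4)
  expect_identical(activation(extractActivations(mi, xi, MaskSpec(fc1 = "all")),
                              "fc1"), xi)

  ## 3x3 all-ones kernel, zero bias, constant input of 1s, valid padding:
  ## every post-ReLU unit equals 9
  mo <- makeToyNetwork(list(list(kind = "conv", out = 1, kernel = 3),
                            list(kind = "relu")),
                       c(1L, 5L, 5L), weightScheme = "all_ones")
  ones <- array(1, dim = c(2, 1, 5, 5))
  a <- activation(extractActivations(mo, ones, MaskSpec(conv1 = "all")), "conv1")
  expect_identical(dim(a), c(2L, 1L, 3L, 3L))
  expect_true(all(a == 9))
})

test_that("masked extraction equals slicing the full extraction, deterministically", {
  m <- twoConvNet()
  x <- randBatch(3, c(1, 10, 10), seed = 5)
  full <- extractActivations(m, x, MaskSpec(conv1 = "all", conv2 = "all",
                                            fc1 = "all"))
  sub <- extractActivations(m, x, MaskSpec(conv1 = c(1)))
  expect_identical(activation(sub, "conv1"),
                   activation(full, "conv1")[, 2, , , drop = FALSE])
  sub2 <- extractActivations(m, x, MaskSpec(conv2 = c(0, 2)))
  expect_identical(activation(sub2, "conv2"),
                   activation(full, "conv2")[, c(1, 3), , , drop = FALSE])
  ## two calls are bit-identical
  again <- extractActivations(m, x, MaskSpec(conv1 = "all", conv2 = "all",
                                             fc1 = "all"))
  expect_identical(again@layers, full@layers)
  ## binding errors
  expect_error(extractActivations(m, x, MaskSpec(nope = "all")),
               "nope", class = "dnnmapr_binding_error")
  expect_error(extractActivations(m, x, MaskSpec(conv1 = c(7))),
               class = "dnnmapr_binding_error")
})

test_that("pre-ReLU extraction differs from the post-ReLU default where negative", {
  m <- twoConvNet()
  x <- randBatch(2, c(1, 10, 10), seed = 6)
  post <- activation(extractActivations(m, x, MaskSpec(conv1 = "all")), "conv1")
  pre <- activation(extractActivations(m, x, MaskSpec(conv1 = "all"),
                                       postRelu = FALSE), "conv1")
  expect_identical(post, pmax(pre, 0))
  expect_true(any(pre < 0))
})

test_that("summarization collapses spatial axes with hand-checked values", {
  a <- array(0, dim = c(1, 1, 2, 2))
  a[1, 1, , ] <- matrix(c(1, 3, 2, 4), 2)   # channel map [[1,2],[3,4]]
  st <- ActivationStore(list(conv1 = a), "s1")
  expect_equal(summarizeActivation(st, "mean")$conv1[1, 1], 2.5)
  expect_equal(summarizeActivation(st, "max")$conv1[1, 1], 4)
  expect_identical(dim(summarizeActivation(st, "none")$conv1), c(1L, 4L))
  ## 1-D layer with mean: unchanged
  fc <- matrix(rnorm(6), 2, 3)
  stf <- ActivationStore(list(fc1 = fc), c("s1", "s2"))
  expect_identical(summarizeActivation(stf, "mean")$fc1, fc)
  expect_error(summarizeActivation(st, "median"),
               class = "dnnmapr_usage_error")
})

test_that("PCA reduction matches an eigendecomposition oracle", {
  ## collinear points: one component explains everything
  line <- cbind(1:10, 2 * (1:10) + 3)
  rd <- reduceDimension(line, 1)
  expect_equal(rd$explainedVarianceRatio, 1.0, tolerance = 1e-12)

  set.seed(7)
  X <- matrix(rnorm(100), 20, 5)
  rd <- reduceDimension(X, 5)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values   # independent oracle
  compVar <- apply(rd$transformed, 2, stats::var)
  expect_equal(unname(compVar), ev, tolerance = 1e-8)
  expect_true(all(diff(rd$explainedVarianceRatio) <= 1e-12))
  expect_lte(sum(rd$explainedVarianceRatio), 1 + 1e-12)
  expect_error(reduceDimension(X, 6), class = "dnnmapr_usage_error")
})

test_that("PCA fit on training rows never reads held-out rows", {
  set.seed(8)
  X <- matrix(rnorm(200), 40, 5)
  tr <- 1:30
  rd1 <- reduceDimension(X, 3, fitOn = tr)
  X2 <- X
  X2[31:40, ] <- X2[31:40, ] + matrix(rnorm(50, sd = 10), 10, 5)
  rd2 <- reduceDimension(X2, 3, fitOn = tr)
  expect_identical(rd1$transformed[tr, ], rd2$transformed[tr, ])
  expect_identical(rd1$explainedVarianceRatio, rd2$explainedVarianceRatio)
})

test_that("ablation zeroes masked channels and matches the bias-propagation oracle", {
  m <- twoConvNet()
  x <- randBatch(3, c(1, 10, 10), seed = 9)

  ## zero-influence channel: silence a channel, then silence the weights
  ## feeding from it -- outputs must match; simpler exact case: ablate a
  ## channel whose outgoing weights we zero manually
  m0 <- m
  m0@layers$conv2$weights[, 2, , ] <- 0   # channel 1 (0-based) has no influence
  abl <- ablateChannels(m0, MaskSpec(conv1 = c(1)))
  expect_identical(networkForward(abl, x)$output,
                   networkForward(m0, x)$output)

  ## ablating ALL first-layer channels == feeding zeros into layer 2
  ablAll <- ablateChannels(m, MaskSpec(conv1 = "all"))
  zshape <- dim(networkForward(m, x, upTo = "conv1")$output)
  cur <- array(0, dim = zshape)
  for (ln in layerNames(m)[-1]) {
    sub <- new("NetworkModel", name = "t", inputShape = dim(cur)[-1],
               layers = m@layers[ln], ablation = list())
    cur <- networkForward(sub, cur)$output
  }
  expect_identical(networkForward(ablAll, x)$output, cur)

  ## reading back the ablated layer gives all-zero masked channels
  st <- extractActivations(ablateChannels(m, MaskSpec(conv1 = c(0))), x,
                           MaskSpec(conv1 = c(0)))
  expect_true(all(activation(st, "conv1") == 0))

  ## idempotence: ablating the same mask twice equals once
  once <- ablateChannels(m, MaskSpec(conv1 = c(0, 2)))
  twiceA <- ablateChannels(once, MaskSpec(conv1 = c(0, 2)))
  expect_identical(networkForward(twiceA, x)$output,
                   networkForward(once, x)$output)
  ## original model untouched
  expect_length(m@ablation, 0)
})

test_that("occlusion receptive fields sit inside the theoretical field", {
  ## identity linear 'image' layer: RF of unit i is exactly pixel i
  mi <- makeToyNetwork(list(list(kind = "linear", out = 16)),
                       c(1L, 4L, 4L), weightScheme = "identity")
  probe <- array(1, dim = c(1, 4, 4))
  est <- estimateEmpiricalRF(mi, list(layer = "fc1", channel = 6), probe)
  ## feature 6 (0-based) = flat index 7 = (channel-fastest) row 2, col 1
  expect_false(est@empty)
  expect_identical(est@extent, c(2L, 1L, 2L, 1L))

  ## conv units: empirical within theoretical over a grid
  m <- twoConvNet()
  probe <- array(runif(100), dim = c(1, 10, 10))
  for (ch in 0:2) for (r in c(0L, 2L)) for (cc in c(0L, 2L)) {
    unit <- list(layer = "conv2", channel = ch, row = r, col = cc)
    emp <- estimateEmpiricalRF(m, unit, probe)
    theo <- theoreticalReceptiveField(m, unit)
    if (!emp@empty) {
      expect_gte(emp@extent[1], theo[1]); expect_gte(emp@extent[2], theo[2])
      expect_lte(emp@extent[3], theo[3]); expect_lte(emp@extent[4], theo[4])
    }
  }

  ## zero-weight unit: empty-extent flag
  mz <- twoConvNet()
  mz@layers$conv1$weights[1, , , ] <- 0
  mz@layers$conv1$bias[1] <- 0
  ez <- estimateEmpiricalRF(mz, list(layer = "conv1", channel = 0, row = 1,
                                     col = 1), probe)
  expect_true(ez@empty)
  expect_error(estimateEmpiricalRF(m, list(layer = "conv2", channel = 0,
                                           row = 0, col = 0), probe,
                                   stride = 0),
               class = "dnnmapr_usage_error")
})

test_that("fine-tuning freezes layers bit-exactly and learns separable data", {
  dd <- makeCategoryDataset(100, "linear_margin", seed = 5)
  base <- makeToyNetwork(list(list(kind = "linear", out = 3)), 2L, seed = 6)

  ## lr = 0: nothing moves
  ft0 <- fineTune(base, list(outDim = 2), dd$features, dd$labels,
                  epochs = 3, lr = 0, seed = 7)
  expect_identical(ft0$model@layers$fc1$weights, base@layers$fc1$weights)

  ## frozen layer bit-identical, head learns, history has one loss per epoch
  ft <- fineTune(base, list(outDim = 2), dd$features, dd$labels,
                 frozen = "fc1", epochs = 200, lr = 0.5, seed = 7)
  expect_identical(ft$model@layers$fc1$weights, base@layers$fc1$weights)
  expect_false(identical(ft$model@layers$head$weights,
                         ft0$model@layers$head$weights))
  expect_length(ft$history, 200)
  pred <- apply(networkForward(ft$model, dd$features)$output, 1, which.max)
  expect_equal(mean(c("a", "b")[pred] == dd$labels), 1.0)
  expect_error(fineTune(base, list(outDim = 2), dd$features, dd$labels,
                        frozen = "conv9", epochs = 1, lr = 0.1),
               class = "dnnmapr_usage_error")
})
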