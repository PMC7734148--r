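test_that("top-stimulus ranking sorts by activation with stable ties", {
  a <- array(0, dim = c(3, 1, 1, 1))
  a[, 1, 1, 1] <- c(0.1, 0.9, 0.5)
  st <- ActivationStore(list(conv1 = a), c("s1", "s2", "s3"))
  top <- findTopStimuli(st, list(layer = "conv1", channel = 0), k = 2)
  expect_identical(top$stim_id, c("s2", "s3"))

  ## full ranking agrees with a brute-force sort oracle
  set.seed(17)
  n <- 25
  vals <- runif(n)
  af <- array(vals, dim = c(n, 1, 1, 1))
  stf <- ActivationStore(list(conv1 = af), sprintf("s%02d", 1:n))
  full <- findTopStimuli(stf, list(layer = "conv1", channel = 0), k = n)
  expect_identical(full$stim_id, sprintf("s%02d", order(vals, decreasing = TRUE)))
  expect_identical(full$activation, sort(vals, decreasing = TRUE))

  ## all equal: order equals stimulus order
  ae <- array(1, dim = c(4, 1, 1, 1))
  ste <- ActivationStore(list(conv1 = ae), c("a", "b", "c", "d"))
  expect_identical(findTopStimuli(ste, list(layer = "conv1", channel = 0),
                                  k = 4)$stim_id, c("a", "b", "c", "d"))
  expect_error(findTopStimuli(ste, list(layer = "conv1", channel = 0), k = 5),
               class = "dnnmapr_usage_error")
  expect_error(findTopStimuli(ste, list(layer = "conv9", channel = 0), k = 1),
               class = "dnnmapr_binding_error")
})

test_that("store-based and model-based top-stimulus queries agree", {
  m <- twoConvNet()
  x <- randBatch(8, c(1, 10, 10), seed = 18)
  store <- extractActivations(m, x, MaskSpec(conv2 = "all"))
  unit <- list(layer = "conv2", channel = 1)
  fromStore <- findTopStimuli(store, unit, k = 8)
  fromModel <- findTopStimuli(list(model = m, batch = x), unit, k = 8)
  expect_identical(fromStore, fromModel)
})

test_that("vanilla saliency equals the weight vector of a single linear unit", {
  w <- c(0.5, -1.2, 3, 0)
  m <- linearUnitNet(w)
  sal <- computeSaliency(m, rnorm(4), list(layer = "fc1", channel = 0))
  expect_lt(max(abs(as.numeric(values(sal)) - w)), 1e-6)
})

test_that("saliency matches finite differences and respects the receptive field", {
  m <- twoConvNet()
  set.seed(19)
  stim <- array(runif(100), dim = c(1, 10, 10))
  units <- expand.grid(ch = 0:2, r = c(0L, 2L), cc = c(1L, 2L))
  for (i in seq_len(nrow(units))) {
    unit <- list(layer = "conv2", channel = units$ch[i],
                 row = units$r[i], col = units$cc[i])
    sal <- values(computeSaliency(m, stim, unit))
    expect_identical(dim(sal), dim(stim))          # shape contract
    ## central finite differences with a step small enough to stay on one
    ## side of every ReLU kink for this probe
    eps <- 1e-4
    fd <- array(0, dim = dim(stim))
    act <- function(x) {
      o <- networkForward(m, array(x, dim = c(1, dim(x))), upTo = "conv2")$output
      o[1, units$ch[i] + 1, units$r[i] + 1, units$cc[i] + 1]
    }
    theo <- theoreticalReceptiveField(m, unit)
    for (r in (theo[1]:theo[3]) + 1L) for (cc in (theo[2]:theo[4]) + 1L) {
      xp <- stim; xp[1, r, cc] <- xp[1, r, cc] + eps
      xm <- stim; xm[1, r, cc] <- xm[1, r, cc] - eps
      fd[1, r, cc] <- (act(xp) - act(xm)) / (2 * eps)
    }
    scale <- max(abs(fd), 1e-8)
    expect_lt(max(abs(sal - fd)) / scale, 1e-3)
    ## exactly zero outside the theoretical receptive field
    inside <- array(FALSE, dim = dim(stim))
    inside[1, (theo[1]:theo[3]) + 1L, (theo[2]:theo[4]) + 1L] <- TRUE
    expect_true(all(sal[!inside] == 0))
  }
})

test_that("guided backprop equals vanilla on an all-positive network", {
  m <- makeToyNetwork(list(list(kind = "conv", out = 2, kernel = 3),
                           list(kind = "relu"),
                           list(kind = "linear", out = 3)),
                      c(1L, 6L, 6L), weightScheme = "all_ones")
  stim <- array(runif(36) + 0.1, dim = c(1, 6, 6))   # strictly positive
  unit <- list(layer = "fc1", channel = 1)
  v <- values(computeSaliency(m, stim, unit, "vanilla"))
  g <- values(computeSaliency(m, stim, unit, "guided"))
  expect_identical(v, g)
  ## and both match finite differences
  act <- function(x)
    networkForward(m, array(x, dim = c(1, dim(x))))$output[1, 2]
  fd <- array(0, dim = dim(stim))
  for (r in 1:6) for (cc in 1:6) {
    xp <- stim; xp[1, r, cc] <- xp[1, r, cc] + 1e-3
    xm <- stim; xm[1, r, cc] <- xm[1, r, cc] - 1e-3
    fd[1, r, cc] <- (act(xp) - act(xm)) / 2e-3
  }
  expect_lt(max(abs(v - fd)) / max(abs(fd)), 1e-4)
})

test_that("synthesis climbs the activation of every probed unit", {
  m <- twoConvNet()
  for (unit in list(list(layer = "conv1", channel = 0),
                    list(layer = "conv2", channel = 2),
                    list(layer = "fc1", channel = 1))) {
    res <- synthesizeOptimalStimulus(m, unit, nIter = 40, seed = 4)
    expect_length(res@trajectory, 41)
    expect_gte(res@trajectory[41], res@trajectory[1])
    ## recorded final activation equals a fresh forward pass
    bu <- list(layer = unit$layer, channel = unit$channel)
    store <- extractActivations(m, array(res@stimulus,
                                         dim = c(1, dim(res@stimulus))),
                                do.call(MaskSpec, stats::setNames(
                                  list(unit$channel), unit$layer)))
    fresh <- summarizeActivation(store, "mean")[[unit$layer]][1, 1]
    expect_lt(abs(fresh - res@trajectory[41]), 1e-5)
  }
})

test_that("synthesis on a linear unit converges to the weight direction", {
  set.seed(20)
  w <- rnorm(16)
  m <- linearUnitNet(w)
  res <- synthesizeOptimalStimulus(m, list(layer = "fc1", channel = 0),
                                   nIter = 100, blurSigma = 0)
  cosine <- abs(sum(res@stimulus * w)) / sqrt(sum(res@stimulus^2) * sum(w^2))
  expect_gte(cosine, 0.99)
  ## no decay, no blur: trajectory strictly increasing
  mono <- synthesizeOptimalStimulus(m, list(layer = "fc1", channel = 0),
                                    nIter = 20, l2Decay = 0, blurSigma = 0)
  expect_true(all(diff(mono@trajectory) > 0))
  ## determinism: same seed and config -> bit-identical
  a <- synthesizeOptimalStimulus(m, list(layer = "fc1", channel = 0),
                                 nIter = 10, seed = 5)
  b <- synthesizeOptimalStimulus(m, list(layer = "fc1", channel = 0),
                                 nIter = 10, seed = 5)
  expect_identical(a@stimulus, b@stimulus)
  expect_identical(a@trajectory, b@trajectory)
})
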