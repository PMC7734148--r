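## Shared fixture builders; everything is generated in code at test time.

## Two-conv toy net on a small grayscale input, deterministic from seed.
twoConvNet <- function(seed = 3L, inShape = c(1L, 10L, 10L)) {
  makeToyNetwork(
    list(list(kind = "conv", out = 4, kernel = 3), list(kind = "relu"),
         list(kind = "pool", size = 2),
         list(kind = "conv", out = 3, kernel = 2), list(kind = "relu"),
         list(kind = "linear", out = 5)),
    inputShape = inShape, seed = seed)
}

## Single linear unit with a known weight vector.
linearUnitNet <- function(w) {
  makeToyNetwork(list(list(kind = "linear", out = 1,
                           weights = matrix(w, nrow = 1), bias = 0)),
                 inputShape = length(w), weightScheme = "custom")
}

randBatch <- function(n, shape, seed = 1L) {
  set.seed(seed)
  array(runif(n * prod(shape)), dim = c(n, shape))
}

## Noiseless linear linkage Y = X %*% W for encoding-recovery checks.
linkageProblem <- function(n = 60, p = 3, q = 2, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  W <- matrix(rnorm(p * q), p, q)
  list(X = X, W = W, Y = ResponseMatrix(X %*% W))
}
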