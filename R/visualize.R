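## ---------------------------------------------------------------------------
## Characterizing unit preferences: top stimuli, gradient saliency,
## optimal-stimulus synthesis.
## ---------------------------------------------------------------------------

#' Rank stimuli by a unit's activation
#'
#' Returns the k stimuli that drive a unit (or a channel) most, sorted by
#' activation descending with ties broken by ascending stimulus order.
#' Channel-level queries collapse the channel's spatial map with the given
#' summary (default mean). Accepts either a precomputed
#' \linkS4class{ActivationStore} or a model plus stimulus batch; both
#' routes give identical rankings on the same activations.
#'
#' @param x an \linkS4class{ActivationStore}, or a list
#'   \code{list(model = NetworkModel, batch = array, table = StimulusTable)}.
#' @param unit list(layer, channel[, row, col]), 0-based. For a store, the
#'   channel index addresses the store's (possibly masked) channel axis.
#' @param k number of stimuli to return (<= n_stim).
#' @param summary "mean" or "max" spatial summary for channel-level queries.
#' @return data.frame(stim_id, activation), k rows, sorted.
#' @export
findTopStimuli <- function(x, unit, k, summary = c("mean", "max")) {
  summary <- match.arg(summary)
  if (is(x, "ActivationStore")) {
    a <- activation(x, unit$layer)
    d <- dim(a)
    ch <- (unit$channel %||% bindingError("unit must name a channel")) + 1L
    if (ch < 1 || ch > d[2])
      bindingError(sprintf("channel %d out of range [0, %d) for layer '%s'",
                           unit$channel, d[2], unit$layer))
    vals <- if (length(d) == 2) {
      a[, ch]
    } else if (!is.null(unit$row) && !is.null(unit$col)) {
      if (unit$row < 0 || unit$row >= d[3] || unit$col < 0 || unit$col >= d[4])
        bindingError("unit coordinates out of range")
      a[, ch, unit$row + 1L, unit$col + 1L]
    } else {
      f <- if (summary == "mean") mean else max
      apply(a[, ch, , , drop = FALSE], 1, f)
    }
    ids <- x@stimIds
  } else {
    model <- x$model
    bu <- bindUnit(model, unit)
    ## same post-ReLU convention as extractActivations, so both routes agree
    eff <- effectiveLayer(model, bu$layer, postRelu = TRUE)
    out <- networkForward(model, x$batch, upTo = eff)$output
    vals <- if (bu$spatial && is.null(bu$row) && summary == "max")
      apply(out[, bu$ch, , , drop = FALSE], 1, max)
    else unitActivation(out, bu)
    ids <- if (!is.null(x$table)) stimIds(x$table)
           else sprintf("stim%03d", seq_along(vals))
  }
  if (k > length(vals))
    usageError(sprintf("k = %d exceeds the number of stimuli (%d)",
                       k, length(vals)))
  ord <- order(-vals)  # stable: ties keep ascending stimulus order
  data.frame(stim_id = ids[ord[seq_len(k)]],
             activation = vals[ord[seq_len(k)]],
             stringsAsFactors = FALSE)
}

#' Compute a gradient saliency map
#'
#' The gradient of a unit's scalar activation with respect to the input
#' stimulus, computed by backpropagation. \code{"vanilla"} is the raw
#' input-gradient; \code{"guided"} additionally zeroes the gradient through
#' every ReLU where the incoming gradient is negative. Channel-level units
#' differentiate the channel's spatial-mean activation. Sign is preserved
#' (no absolute value); the map has exactly the stimulus's shape.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param stimulus input tensor (c, h, w), (1, c, h, w) or feature vector.
#' @param unit list(layer, channel[, row, col]), 0-based.
#' @param method "vanilla" or "guided".
#' @return a \linkS4class{SaliencyMap}.
#' @export
computeSaliency <- function(model, stimulus, unit,
                            method = c("vanilla", "guided")) {
  method <- match.arg(method)
  bu <- bindUnit(model, unit)
  single <- FALSE
  if (is.null(dim(stimulus))) {
    stimulus <- matrix(stimulus, nrow = 1)
    single <- TRUE
  } else if (length(dim(stimulus)) == 3) {
    stimulus <- array(stimulus, dim = c(1, dim(stimulus)))
    single <- TRUE
  }
  if (length(model@inputShape) == 3 &&
      !identical(dim(stimulus)[-1], as.integer(model@inputShape)))
    bindingError(sprintf("stimulus shape [%s] does not match model input [%s]",
                         paste(dim(stimulus)[-1], collapse = " x "),
                         paste(model@inputShape, collapse = " x ")))
  fw <- networkForward(model, stimulus, keepCache = TRUE, upTo = bu$layer)
  seed <- unitSeedGradient(dim(fw$output) %||%
                             c(1L, length(fw$output)), bu)
  bw <- networkBackward(model, fw$caches, bu$layer, seed,
                        guided = (method == "guided"))
  g <- bw$dInput
  if (!all(is.finite(g))) validationError("non-finite saliency values")
  vals <- if (single) {
    if (length(dim(g)) == 4) array(g[1, , , ], dim = dim(g)[-1])
    else as.array(g[1, ])
  } else as.array(g)
  new("SaliencyMap", values = vals, unit = unit, method = method)
}

## Gaussian blur of a (c, h, w) tensor, zero-padded "same" convolution.
gaussianBlur <- function(x, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  out <- x
  for (ch in seq_len(d[1])) {
    m <- out[ch, , ]
    m <- apply(m, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
    m[is.na(m)] <- 0
    ## zero-padded: filter() drops edges to NA; recompute edges explicitly
    m2 <- t(apply(m, 1, function(row) {
      v <- as.numeric(stats::filter(row, k, sides = 2))
      v[is.na(v)] <- 0
      v
    }))
    out[ch, , ] <- m2
  }
  out
}

#' Synthesize the optimal stimulus of a unit by gradient ascent
#'
#' Starting from seeded uniform noise, repeatedly steps the input along the
#' L2-normalized gradient of the target activation, applies multiplicative
#' weight decay and, optionally, periodic Gaussian blur -- the standard
#' regularized activation-maximization recipe. The activation trajectory
#' (including the initial noise) is recorded, and the final entry equals a
#' fresh forward pass on the returned stimulus.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param unit list(layer, channel[, row, col]), 0-based.
#' @param nIter iterations (>= 1; default 100).
#' @param stepSize gradient-ascent step (default 0.1).
#' @param l2Decay multiplicative decay per iteration (default 0.01).
#' @param blurSigma Gaussian blur sigma in pixels (default 0.5; 0 disables).
#' @param blurEvery blur every this many iterations (default 4).
#' @param seed RNG seed for the initial noise.
#' @return a \linkS4class{SynthesisResult}.
#' @export
synthesizeOptimalStimulus <- function(model, unit, nIter = 100L,
                                      stepSize = 0.1, l2Decay = 0.01,
                                      blurSigma = 0.5, blurEvery = 4L,
                                      seed = 0L) {
  if (nIter < 1) usageError("nIter must be >= 1")
  bu <- bindUnit(model, unit)
  shp <- model@inputShape
  ## low-amplitude noise start: ascent, not the random start, should set the
  ## scale of the result (large starts let the weight decay dominate early)
  x <- withSeed(seed, array((stats::runif(prod(shp)) - 0.5) * 0.1, dim = shp))
  spatial <- length(shp) == 3
  batchOf <- function(x) if (spatial) array(x, dim = c(1, shp))
                         else matrix(x, nrow = 1)
  act <- function(x)
    unitActivation(networkForward(model, batchOf(x), upTo = bu$layer)$output, bu)
  traj <- numeric(nIter + 1)
  traj[1] <- act(x)
  for (it in seq_len(nIter)) {
    fw <- networkForward(model, batchOf(x), keepCache = TRUE, upTo = bu$layer)
    seedG <- unitSeedGradient(dim(fw$output) %||% c(1L, length(fw$output)), bu)
    g <- networkBackward(model, fw$caches, bu$layer, seedG)$dInput
    g <- if (spatial) array(g[1, , , ], dim = shp) else as.numeric(g[1, ])
    nrm <- sqrt(sum(g^2))
    if (nrm > 0) x <- x + stepSize * g / nrm
    if (l2Decay > 0) x <- x * (1 - l2Decay)
    if (blurSigma > 0 && blurEvery > 0 && it %% blurEvery == 0 && spatial)
      x <- gaussianBlur(x, blurSigma)
    a <- act(x)
    if (!is.finite(a))
      validationError(sprintf("non-finite activation at iteration %d", it))
    traj[it + 1] <- a
  }
  new("SynthesisResult", stimulus = as.array(x), trajectory = traj,
      config = list(n_iter = as.integer(nIter), step_size = stepSize,
                    l2_decay = l2Decay, blur_sigma = blurSigma,
                    blur_every = as.integer(blurEvery),
                    seed = as.integer(seed)))
}
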