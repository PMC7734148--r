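## ---------------------------------------------------------------------------
## Scanning a network: masked activation extraction and unit-level probes.
## ---------------------------------------------------------------------------

## Validate a mask against a model; returns per-layer 1-based channel
## selections. Convolution layers are addressed by their conv name; the
## extraction itself decides whether the post-ReLU output is taken.
bindMask <- function(model, mask) {
  shp <- layerShapes(model)
  out <- list()
  for (ln in names(mask@entries)) {
    if (!ln %in% names(shp))
      bindingError(sprintf("mask references unknown layer '%s' (model has: %s)",
                           ln, paste(names(shp), collapse = ", ")))
    s <- shp[[ln]]
    e <- mask@entries[[ln]]
    nchn <- s[1]
    ch <- if (identical(e$channels, "all")) seq_len(nchn)
          else {
            if (any(e$channels >= nchn))
              bindingError(sprintf(
                "mask channel(s) %s out of range [0, %d) for layer '%s'",
                paste(e$channels[e$channels >= nchn], collapse = ","), nchn, ln))
            e$channels + 1L
          }
    if (!identical(e$units, "all") && length(s) == 3) {
      bad <- e$units[, 1] >= s[2] | e$units[, 2] >= s[3]
      if (any(bad))
        bindingError(sprintf("mask unit(s) out of range for layer '%s'", ln))
    }
    out[[ln]] <- list(channels = ch, units = e$units)
  }
  out
}

## The post-ReLU convention: when a conv layer is immediately followed by a
## relu layer, "the activation of the conv layer" means the relu output.
effectiveLayer <- function(model, ln, postRelu) {
  lnames <- names(model@layers)
  i <- match(ln, lnames)
  if (postRelu && model@layers[[ln]]$kind == "conv" &&
      i < length(lnames) && model@layers[[lnames[i + 1]]]$kind == "relu")
    lnames[i + 1]
  else ln
}

#' Extract masked activations of a network for a stimulus set
#'
#' Runs the stimulus batch through the network and collects, for every layer
#' named in the mask, the activation tensor restricted to the masked
#' channels. By convention the activation of a convolutional layer is its
#' post-ReLU output (the output after convolution and rectification);
#' \code{postRelu = FALSE} extracts the pre-rectification values instead.
#' Stimulus order is preserved exactly.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param stimuli input batch array (n, c, h, w) / matrix (n, p), or a list
#'   \code{list(batch = ..., table = StimulusTable)}.
#' @param mask a \linkS4class{MaskSpec}.
#' @param postRelu take conv activations after the following ReLU (default).
#' @return an \linkS4class{ActivationStore}.
#' @export
extractActivations <- function(model, stimuli, mask, postRelu = TRUE) {
  table <- NULL
  if (is.list(stimuli) && !is.null(stimuli$batch)) {
    table <- stimuli$table
    stimuli <- stimuli$batch
  }
  bound <- bindMask(model, mask)
  eff <- vapply(names(bound), function(ln) effectiveLayer(model, ln, postRelu),
                character(1))
  fw <- networkForward(model, stimuli, record = unique(unname(eff)))
  n <- dim(stimuli)[1] %||% nrow(stimuli)
  ids <- if (!is.null(table)) stimIds(table) else sprintf("stim%03d", seq_len(n))
  layers <- list()
  for (ln in names(bound)) {
    a <- fw$acts[[eff[[ln]]]]
    ch <- bound[[ln]]$channels
    a <- if (length(dim(a)) == 2) a[, ch, drop = FALSE]
         else a[, ch, , , drop = FALSE]
    layers[[ln]] <- a
  }
  ActivationStore(layers, ids, provenance = list(
    model = model@name,
    mask = paste(vapply(names(bound), function(ln)
      sprintf("%s[%s]", ln, paste(bound[[ln]]$channels - 1L, collapse = ",")),
      character(1)), collapse = ";"),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Summarize activation tensors into stimulus-by-feature matrices
#'
#' Collapses the spatial axes of each layer tensor: \code{"mean"} and
#' \code{"max"} reduce every channel map to one number per stimulus
#' (n_stim x n_chn); \code{"none"} flattens all non-stimulus axes
#' (n_stim x n_chn * prod(spatial)). 1-D layers pass through unchanged for
#' mean/max.
#'
#' @param store an \linkS4class{ActivationStore}.
#' @param method "mean", "max" or "none".
#' @return named list of numeric matrices, one per layer.
#' @export
summarizeActivation <- function(store, method = c("mean", "max", "none")) {
  if (length(store@layers) == 0) usageError("empty activation store")
  method <- tryCatch(match.arg(method),
                     error = function(e) usageError("unknown summary method"))
  lapply(store@layers, function(a) {
    d <- dim(a)
    if (length(d) == 2 && method != "none") return(a)
    if (method == "none") return(matrix(as.vector(a), nrow = d[1]))
    n <- d[1]; nc <- d[2]
    m <- matrix(0, n, nc)
    f <- if (method == "mean") mean else max
    for (s in seq_len(n)) for (ch in seq_len(nc))
      m[s, ch] <- f(a[s, ch, , ])
    m
  })
}

#' Reduce feature dimensionality by principal component analysis
#'
#' Projects a samples-by-features matrix onto its leading principal axes.
#' The axes may be fit on all rows (global mode) or on a training subset
#' only (\code{fitOn}), in which case held-out rows are transformed with the
#' training-fit axes and never influence them.
#'
#' @param X numeric matrix (n_samples x n_features).
#' @param nComponents number of components, between 1 and
#'   min(n_fit_samples, n_features).
#' @param fitOn optional integer row subset used to fit the axes.
#' @return list with \code{transformed} (n_samples x nComponents),
#'   \code{explainedVarianceRatio} (non-increasing, sums to <= 1), and
#'   \code{fitOn}.
#' @export
reduceDimension <- function(X, nComponents, fitOn = NULL) {
  X <- as.matrix(X)
  fit <- if (is.null(fitOn)) X else X[fitOn, , drop = FALSE]
  lim <- min(nrow(fit), ncol(X))
  if (nComponents < 1 || nComponents > lim)
    usageError(sprintf("nComponents must be in [1, %d]", lim))
  pc <- stats::prcomp(fit, center = TRUE, scale. = FALSE)
  k <- seq_len(nComponents)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(transformed = scale(X, center = pc$center, scale = FALSE) %*%
         pc$rotation[, k, drop = FALSE],
       explainedVarianceRatio = evr[k],
       fitOn = fitOn)
}

#' Ablate channels or units of a network
#'
#' Returns a copy of the model whose forward pass multiplies the masked
#' channels' (or units') outputs by zero at the masked layer; everything
#' else is unchanged and the original model is not modified. Ablation is
#' idempotent: applying the same mask twice equals applying it once.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param mask a \linkS4class{MaskSpec} naming the layers/channels/units to
#'   silence.
#' @return a new \linkS4class{NetworkModel} with the ablation attached.
#' @export
ablateChannels <- function(model, mask) {
  bindMask(model, mask)  # binding errors surface here
  abl <- model@ablation
  for (ln in names(mask@entries)) {
    e <- mask@entries[[ln]]
    prev <- abl[[ln]]
    if (is.null(prev)) {
      abl[[ln]] <- list(channels = e$channels, units = e$units)
    } else {
      ch <- if (identical(prev$channels, "all") || identical(e$channels, "all"))
        "all" else sort(unique(c(prev$channels, e$channels)))
      un <- if (identical(prev$units %||% "all", "all") ||
                identical(e$units, "all")) "all"
            else unique(rbind(prev$units, e$units))
      abl[[ln]] <- list(channels = ch, units = un)
    }
  }
  initialize(model, ablation = abl)
}

#' Estimate the empirical receptive field of a unit by occlusion
#'
#' Slides a zeroing patch over the probe image, records the absolute change
#' of the unit's activation at every occluder position, and returns the
#' bounding box of positions whose change reaches \code{thresholdFrac}
#' times the maximum change. If occlusion never changes the response the
#' estimate is flagged empty rather than returned as a zero-area box.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param unit list(layer, channel, row, col), 0-based.
#' @param probeImage input tensor (c, h, w) or (1, c, h, w).
#' @param patchSize occluder side length in pixels (default 1).
#' @param stride occluder stride in pixels (default 1, must be >= 1).
#' @param thresholdFrac fraction of the maximal response change a position
#'   must reach to count as inside the field, in (0, 1].
#' @return an \linkS4class{RFEstimate}.
#' @export
estimateEmpiricalRF <- function(model, unit, probeImage, patchSize = 1L,
                                stride = 1L, thresholdFrac = 0.05) {
  if (stride < 1) usageError("stride must be >= 1")
  if (thresholdFrac <= 0 || thresholdFrac > 1)
    usageError("thresholdFrac must be in (0, 1]")
  bu <- bindUnit(model, unit)
  if (length(dim(probeImage)) == 3)
    probeImage <- array(probeImage, dim = c(1, dim(probeImage)))
  d <- dim(probeImage)
  if (patchSize > min(d[3], d[4]))
    usageError("patchSize must not exceed the image side")
  base <- unitActivation(
    networkForward(model, probeImage, upTo = bu$layer)$output, bu)
  pos_r <- seq(1L, d[3] - patchSize + 1L, by = stride)
  pos_c <- seq(1L, d[4] - patchSize + 1L, by = stride)
  delta <- matrix(0, length(pos_r), length(pos_c))
  for (i in seq_along(pos_r)) for (j in seq_along(pos_c)) {
    x <- probeImage
    x[, , pos_r[i]:(pos_r[i] + patchSize - 1L),
         pos_c[j]:(pos_c[j] + patchSize - 1L)] <- 0
    a <- unitActivation(networkForward(model, x, upTo = bu$layer)$output, bu)
    delta[i, j] <- abs(a - base)
  }
  mx <- max(delta)
  if (mx == 0)
    return(new("RFEstimate", unit = unit, extent = NA_integer_,
               empty = TRUE, deltaMap = delta))
  hit <- which(delta >= thresholdFrac * mx, arr.ind = TRUE)
  top <- pos_r[min(hit[, 1])] - 1L
  left <- pos_c[min(hit[, 2])] - 1L
  bottom <- pos_r[max(hit[, 1])] + patchSize - 2L
  right <- pos_c[max(hit[, 2])] + patchSize - 2L
  new("RFEstimate", unit = unit,
      extent = as.integer(c(top, left, min(bottom, d[3] - 1L),
                            min(right, d[4] - 1L))),
      empty = FALSE, deltaMap = delta)
}

## One-hot encode labels (column order = sorted unique labels).
oneHot <- function(y) {
  lev <- sort(unique(as.character(y)))
  m <- matrix(0, length(y), length(lev))
  m[cbind(seq_along(y), match(as.character(y), lev))] <- 1
  colnames(m) <- lev
  m
}

softmaxXent <- function(logits, target) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  loss <- -mean(rowSums(target * log(pmax(p, 1e-300))))
  list(loss = loss, grad = (p - target) / nrow(logits), prob = p)
}

#' Fine-tune a network on a new task with frozen layers
#'
#' Attaches a fresh linear task head after the last layer (or a named
#' attachment layer), then trains head and unfrozen layers by full-batch
#' gradient descent on the softmax cross-entropy (classification) or mean
#' squared error (regression) of the provided targets. Frozen layers keep
#' their weights bit-identical. Initialization and training are fully
#' determined by \code{seed}.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param head list(outDim, attachAfter = NULL, name = "head").
#' @param stimuli training input batch.
#' @param targets class labels (factor/character/integer) or a numeric
#'   target matrix for regression.
#' @param frozen character vector of layer names to freeze.
#' @param epochs number of full-batch epochs.
#' @param lr learning rate.
#' @param seed RNG seed for head initialization.
#' @return list with \code{model} (tuned network including head) and
#'   \code{history} (per-epoch loss, length \code{epochs}).
#' @export
fineTune <- function(model, head, stimuli, targets, frozen = character(),
                     epochs = 50L, lr = 0.1, seed = 0L) {
  bad <- setdiff(frozen, names(model@layers))
  if (length(bad))
    usageError(sprintf("unknown frozen layer(s): %s", paste(bad, collapse = ", ")))
  attach <- head$attachAfter %||% utils::tail(names(model@layers), 1)
  if (!attach %in% names(model@layers))
    usageError(sprintf("unknown attachment layer '%s'", attach))
  keep <- seq_len(match(attach, names(model@layers)))
  layers <- model@layers[keep]
  shp <- layerShapes(model)[[attach]]
  inDim <- prod(shp)
  classify <- !is.numeric(targets) || is.null(dim(targets))
  tg <- if (classify) oneHot(targets) else as.matrix(targets)
  outDim <- head$outDim %||% ncol(tg)
  if (nrow(tg) != (dim(stimuli)[1] %||% nrow(stimuli)))
    usageError("targets must align with stimuli")
  hname <- head$name %||% "head"
  layers[[hname]] <- withSeed(seed, list(
    kind = "linear",
    weights = matrix(stats::rnorm(outDim * inDim, sd = sqrt(1 / inDim)),
                     outDim, inDim),
    bias = numeric(outDim)))
  tuned <- new("NetworkModel", name = paste0(model@name, "+", hname),
               inputShape = model@inputShape, layers = layers,
               ablation = model@ablation)
  trainable <- setdiff(names(layers)[vapply(layers, function(l)
    l$kind %in% c("conv", "linear"), logical(1))], frozen)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- networkForward(tuned, stimuli, keepCache = TRUE)
    ls <- if (classify) softmaxXent(fw$output, tg)
          else list(loss = mean((fw$output - tg)^2),
                    grad = 2 * (fw$output - tg) / length(tg))
    bw <- networkBackward(tuned, fw$caches, hname, ls$grad, needParams = TRUE)
    for (ln in trainable) {
      g <- bw$paramGrads[[ln]]
      if (is.null(g)) next
      tuned@layers[[ln]]$weights <-
        tuned@layers[[ln]]$weights - lr * array(g$dW, dim = dim(tuned@layers[[ln]]$weights))
      tuned@layers[[ln]]$bias <- tuned@layers[[ln]]$bias - lr * g$db
    }
    history[ep] <- ls$loss
  }
  list(model = tuned, history = history)
}
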