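## ---------------------------------------------------------------------------
## Deterministic fixtures: toy networks, synthetic stimuli and linked
## synthetic responses with known ground truth. Everything is reproducible
## from its arguments and seed alone; nothing reads the filesystem.
##
## Scale is deliberately small (inputs <= 32x32, <= 3 conv layers, <= 16
## channels) so that every analysis pipeline runs in seconds.
## ---------------------------------------------------------------------------

#' Build a deterministic toy network
#'
#' Constructs a \linkS4class{NetworkModel} from an ordered list of layer
#' descriptors. Layers are auto-named \code{conv1, relu1, pool1, ..., fc1,
#' ...} in order of kind. Weight schemes: \code{"random_gaussian"} (seeded
#' He-scaled normals), \code{"identity"} (linear layers only),
#' \code{"all_ones"} (unit weights, zero bias) or \code{"custom"} (each
#' conv/linear descriptor carries \code{weights}/\code{bias}).
#'
#' @param arch list of descriptors, e.g. \code{list(list(kind = "conv",
#'   out = 4, kernel = 3), list(kind = "relu"), list(kind = "linear",
#'   out = 2))}. Conv descriptors accept \code{kernel}, \code{stride},
#'   \code{pad}; pool descriptors \code{size}, \code{stride},
#'   \code{method}.
#' @param inputShape c(channels, height, width), or a feature count for
#'   vector-input models.
#' @param seed RNG seed; fully determines all weights.
#' @param weightScheme "random_gaussian", "identity", "all_ones" or
#'   "custom".
#' @param name model name.
#' @return a \linkS4class{NetworkModel}.
#' @export
makeToyNetwork <- function(arch, inputShape, seed = 0L,
                           weightScheme = c("random_gaussian", "identity",
                                            "all_ones", "custom"),
                           name = "toynet") {
  weightScheme <- match.arg(weightScheme)
  counts <- c(conv = 0L, relu = 0L, pool = 0L, linear = 0L)
  shp <- as.integer(inputShape)
  layers <- withSeed(seed, {
    out <- list()
    for (a in arch) {
      kind <- a$kind
      if (!kind %in% names(counts))
        validationError(sprintf("unknown layer kind '%s'", kind))
      counts[kind] <- counts[kind] + 1L
      ln <- if (kind == "linear") sprintf("fc%d", counts[kind])
            else sprintf("%s%d", kind, counts[kind])
      ly <- switch(kind,
        conv = {
          if (length(shp) != 3)
            validationError(sprintf("layer %s: conv requires image input", ln))
          k <- rep(as.integer(a$kernel %||% 3L), length.out = 2)
          oc <- as.integer(a$out %||% 1L)
          st <- rep(as.integer(a$stride %||% 1L), length.out = 2)
          pd <- rep(as.integer(a$pad %||% 0L), length.out = 2)
          fanin <- shp[1] * prod(k)
          W <- switch(weightScheme,
            random_gaussian = array(stats::rnorm(oc * fanin,
                                                 sd = sqrt(2 / fanin)),
                                    dim = c(oc, shp[1], k)),
            all_ones = array(1, dim = c(oc, shp[1], k)),
            custom = a$weights %||%
              validationError(sprintf("layer %s: custom weights missing", ln)),
            identity = validationError("identity scheme applies to linear layers only"))
          b <- switch(weightScheme, custom = a$bias %||% numeric(oc),
                      numeric(oc))
          newH <- (shp[2] + 2 * pd[1] - k[1]) %/% st[1] + 1L
          newW <- (shp[3] + 2 * pd[2] - k[2]) %/% st[2] + 1L
          if (newH < 1 || newW < 1)
            validationError(sprintf("layer %s: output shape collapses", ln))
          shp <- c(oc, newH, newW)
          list(kind = "conv", weights = W, bias = b, stride = st, pad = pd)
        },
        relu = list(kind = "relu"),
        pool = {
          sz <- rep(as.integer(a$size %||% 2L), length.out = 2)
          st <- rep(as.integer(a$stride %||% sz[1]), length.out = 2)
          shp <- c(shp[1], (shp[2] - sz[1]) %/% st[1] + 1L,
                    (shp[3] - sz[2]) %/% st[2] + 1L)
          list(kind = "pool", method = a$method %||% "max", size = sz,
               stride = st)
        },
        linear = {
          fanin <- prod(shp)
          oc <- as.integer(a$out %||% fanin)
          W <- switch(weightScheme,
            random_gaussian = matrix(stats::rnorm(oc * fanin,
                                                  sd = sqrt(1 / fanin)),
                                     oc, fanin),
            identity = {
              if (oc != fanin)
                validationError("identity scheme requires out == in")
              diag(fanin)
            },
            all_ones = matrix(1, oc, fanin),
            custom = a$weights %||%
              validationError(sprintf("layer %s: custom weights missing", ln)))
          b <- switch(weightScheme, custom = a$bias %||% numeric(oc),
                      numeric(oc))
          shp <- oc
          list(kind = "linear", weights = W, bias = b)
        })
      out[[ln]] <- ly
    }
    out
  })
  model <- new("NetworkModel", name = name, inputShape = as.integer(inputShape),
               layers = layers, ablation = list())
  layerShapes(model)  # raises on inconsistent shapes
  model
}

#' Generate synthetic stimuli with an aligned stimulus table
#'
#' \code{"noise"}: iid uniform pixels. \code{"gabor_bank"}: oriented
#' sinusoidal gratings under a Gaussian envelope, orientations evenly
#' spaced over [0, 180), recorded in the \code{orientation_deg} attribute.
#' \code{"blob"}: one localized Gaussian bump per stimulus at a seeded
#' position, recorded in the \code{blob_row}/\code{blob_col} attributes
#' (0-based; the bump peak is the pixel argmax).
#'
#' @param n number of stimuli.
#' @param shape c(channels, height, width).
#' @param seed RNG seed.
#' @param kind "noise", "gabor_bank" or "blob".
#' @return list(batch = array (n, c, h, w), table =
#'   \linkS4class{StimulusTable}).
#' @export
makeSyntheticStimuli <- function(n, shape = c(1L, 16L, 16L), seed = 0L,
                                 kind = c("noise", "gabor_bank", "blob")) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  c0 <- shape[1]; h <- shape[2]; w <- shape[3]
  ids <- sprintf("stim%03d", seq_len(n))
  df <- data.frame(stim_id = ids, onset = (seq_len(n) - 1) * 2,
                   duration = rep(1, n), stringsAsFactors = FALSE)
  batch <- array(0, dim = c(n, shape))
  withSeed(seed, {
    if (kind == "noise") {
      batch[] <- stats::runif(length(batch))
    } else if (kind == "gabor_bank") {
      ori <- (seq_len(n) - 1) * 180 / n
      freq <- 2 / min(h, w)
      yy <- matrix(seq_len(h) - (h + 1) / 2, h, w)
      xx <- t(matrix(seq_len(w) - (w + 1) / 2, w, h))
      env <- exp(-(xx^2 + yy^2) / (2 * (min(h, w) / 4)^2))
      for (i in seq_len(n)) {
        th <- ori[i] * pi / 180
        g <- cos(2 * pi * freq * (xx * cos(th) + yy * sin(th))) * env
        for (ch in seq_len(c0)) batch[i, ch, , ] <- g
      }
      df$orientation_deg <- ori
    } else {
      rr <- sample(2:(h - 1), n, replace = TRUE)
      cc <- sample(2:(w - 1), n, replace = TRUE)
      yy <- matrix(seq_len(h), h, w)
      xx <- t(matrix(seq_len(w), w, h))
      for (i in seq_len(n)) {
        g <- exp(-((yy - rr[i])^2 + (xx - cc[i])^2) / (2 * 1.5^2))
        for (ch in seq_len(c0)) batch[i, ch, , ] <- g
      }
      df$blob_row <- rr - 1L
      df$blob_col <- cc - 1L
    }
  })
  list(batch = batch,
       table = StimulusTable(df, stimDir = ".", stimType = "image"))
}

#' Generate synthetic site responses linearly linked to layer features
#'
#' Emulates the premise of a linear encoding analysis: each site's response
#' is a seeded Gaussian-weighted combination of the layer's mean-summarized
#' channel features plus iid Gaussian noise. The generating weights and
#' noise level are returned as ground truth.
#'
#' @param store an \linkS4class{ActivationStore}.
#' @param layer layer to base the responses on.
#' @param nSites number of measurement sites.
#' @param noiseSd response noise standard deviation (0 = noiseless).
#' @param seed RNG seed.
#' @return list(responses = \linkS4class{ResponseMatrix},
#'   truth = \linkS4class{GroundTruth}).
#' @export
makeLinkedResponses <- function(store, layer, nSites, noiseSd = 0.1,
                                seed = 0L) {
  feats <- summarizeActivation(store, "mean")[[layer]]
  if (is.null(feats)) bindingError(sprintf("layer '%s' not in store", layer))
  p <- ncol(feats)
  withSeed(seed, {
    W <- matrix(stats::rnorm(p * nSites), p, nSites)
    eps <- matrix(stats::rnorm(nrow(feats) * nSites, sd = noiseSd),
                  nrow(feats), nSites)
  })
  Y <- feats %*% W + eps
  list(responses = ResponseMatrix(Y, stimIds = store@stimIds,
                                  siteIds = sprintf("site%03d", seq_len(nSites))),
       truth = new("GroundTruth", weights = W, noiseSd = noiseSd,
                   labelRule = sprintf(
                     "site = %s features %%*%% N(0,1) weights + N(0, %g) noise",
                     layer, noiseSd)))
}

#' Generate a labeled feature dataset for decoding analyses
#'
#' \code{"linear_margin"}: two balanced classes separated along the first
#' feature with a guaranteed margin (class sign times (1 + |N(0,1)|) times
#' half the margin), hence linearly separable by construction.
#' \code{"xor"}: points in the four quadrants labeled by the sign product
#' of the first two features -- balanced but not linearly separable.
#'
#' @param n number of samples (classes balanced to within one).
#' @param rule "linear_margin" or "xor".
#' @param seed RNG seed.
#' @param margin separation between the class supports along feature 1
#'   (linear_margin; default 6, i.e. six noise SDs).
#' @return list(features = n x 2 matrix, labels = character vector,
#'   table = \linkS4class{StimulusTable} carrying the label attribute).
#' @export
makeCategoryDataset <- function(n, rule = c("linear_margin", "xor"),
                                seed = 0L, margin = 6) {
  rule <- match.arg(rule)
  nPos <- ceiling(n / 2)
  lab <- rep(c("a", "b"), length.out = n)
  sgn <- ifelse(lab == "a", 1, -1)
  X <- withSeed(seed, {
    if (rule == "linear_margin") {
      cbind(sgn * (margin / 2) * (1 + abs(stats::rnorm(n)) / 3),
            stats::rnorm(n))
    } else {
      x1 <- stats::runif(n, 0.5, 1.5) * sample(c(-1, 1), n, replace = TRUE)
      q <- ifelse(sgn > 0, 1, -1)  # label = sign(x1 * x2)
      x2 <- stats::runif(n, 0.5, 1.5) * q * sign(x1)
      cbind(x1, x2)
    }
  })
  colnames(X) <- c("f1", "f2")
  ids <- sprintf("stim%03d", seq_len(n))
  tab <- StimulusTable(data.frame(stim_id = ids, label = lab,
                                  stringsAsFactors = FALSE))
  list(features = X, labels = lab, table = tab)
}
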