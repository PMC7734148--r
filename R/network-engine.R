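## ---------------------------------------------------------------------------
## Feed-forward network engine.
##
## Tensors use the (n_stim, channels, height, width) layout; 1-D layer
## outputs are (n_stim, features) matrices. Convolution is implemented by
## im2col: each kernel patch is gathered into a column so the convolution
## becomes one matrix product, and the backward pass is the transposed
## product scattered back through the same index map. All operations are
## deterministic; there is no stochastic layer.
## ---------------------------------------------------------------------------

## Gather-index map for im2col on a (c, h, w) tensor. Patch elements are
## ordered channel-fastest, then kernel row, then kernel column -- the same
## order as flattening the weight array (out, in, kh, kw) per output channel.
im2colIndex <- function(c, h, w, kh, kw, sh, sw) {
  oh <- (h - kh) %/% sh + 1L
  ow <- (w - kw) %/% sw + 1L
  ci <- rep(seq_len(c), times = kh * kw)
  di <- rep(rep(0:(kh - 1L), each = c), times = kw)
  dj <- rep(0:(kw - 1L), each = c * kh)
  off <- ci + c * di + c * h * dj           # patch at top-left (1, 1)
  oi <- rep(0:(oh - 1L), times = ow) * sh
  oj <- rep(0:(ow - 1L), each = oh) * sw
  colbase <- c * oi + c * h * oj
  list(idx = outer(off, colbase, "+"), oh = oh, ow = ow)
}

padInput <- function(x, ph, pw) {           # x: (c, h, w)
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2 * ph, d[3] + 2 * pw))
  out[, (ph + 1):(ph + d[2]), (pw + 1):(pw + d[3])] <- x
  out
}

convForward <- function(layer, x) {         # x: (n, c, h, w)
  W <- layer$weights; b <- layer$bias
  dW <- dim(W)                              # (out, in, kh, kw)
  st <- layer$stride %||% c(1L, 1L); pd <- layer$pad %||% c(0L, 0L)
  n <- dim(x)[1]
  hp <- dim(x)[3] + 2 * pd[1]; wp <- dim(x)[4] + 2 * pd[2]
  map <- im2colIndex(dW[2], hp, wp, dW[3], dW[4], st[1], st[2])
  Wmat <- matrix(W, nrow = dW[1])
  out <- array(0, dim = c(n, dW[1], map$oh, map$ow))
  cols <- vector("list", n)
  for (s in seq_len(n)) {
    xs <- padInput(array(x[s, , , ], dim = dim(x)[2:4]), pd[1], pd[2])
    xc <- matrix(xs[map$idx], nrow = nrow(map$idx))
    cols[[s]] <- xc
    y <- Wmat %*% xc + b
    out[s, , , ] <- array(y, dim = c(dW[1], map$oh, map$ow))
  }
  list(out = out, cache = list(cols = cols, map = map, xdim = dim(x),
                               pad = pd, stride = st))
}

convBackward <- function(layer, cache, dout, needParams = FALSE) {
  W <- layer$weights; dWd <- dim(W)
  Wmat <- matrix(W, nrow = dWd[1])
  map <- cache$map; xd <- cache$xdim; pd <- cache$pad
  n <- xd[1]
  hp <- xd[3] + 2 * pd[1]; wp <- xd[4] + 2 * pd[2]
  dx <- array(0, dim = xd)
  dWacc <- if (needParams) matrix(0, dWd[1], prod(dWd[2:4]))
  dbacc <- if (needParams) numeric(dWd[1])
  av <- as.vector(map$idx)
  for (s in seq_len(n)) {
    dyc <- matrix(dout[s, , , ], nrow = dWd[1])   # (out, oh*ow)
    dxc <- crossprod(Wmat, dyc)                   # (c*kh*kw, oh*ow)
    acc <- rowsum(as.vector(dxc), av)
    dxp <- numeric(xd[2] * hp * wp)
    dxp[as.integer(rownames(acc))] <- acc
    dxp <- array(dxp, dim = c(xd[2], hp, wp))
    dx[s, , , ] <- dxp[, (pd[1] + 1):(pd[1] + xd[3]),
                       (pd[2] + 1):(pd[2] + xd[4])]
    if (needParams) {
      dWacc <- dWacc + tcrossprod(dyc, cache$cols[[s]])
      dbacc <- dbacc + rowSums(dyc)
    }
  }
  list(dx = dx,
       dW = if (needParams) array(dWacc, dim = dWd),
       db = dbacc)
}

reluForward <- function(layer, x) list(out = pmax(x, 0), cache = list(x = x))

reluBackward <- function(layer, cache, dout, guided = FALSE) {
  g <- dout * (cache$x > 0)
  if (guided) g <- g * (dout > 0)
  list(dx = g)
}

poolForward <- function(layer, x) {         # x: (n, c, h, w)
  sz <- layer$size %||% c(2L, 2L); st <- layer$stride %||% sz
  d <- dim(x)
  map <- im2colIndex(1L, d[3], d[4], sz[1], sz[2], st[1], st[2])
  n <- d[1]; c <- d[2]
  out <- array(0, dim = c(n, c, map$oh, map$ow))
  amax <- if (identical(layer$method %||% "max", "max"))
    array(0L, dim = c(n, c, map$oh * map$ow))
  for (s in seq_len(n)) for (ch in seq_len(c)) {
    xc <- matrix(x[s, ch, , ][map$idx], nrow = nrow(map$idx))
    if (identical(layer$method %||% "max", "max")) {
      w <- max.col(t(xc), ties.method = "first")
      amax[s, ch, ] <- map$idx[cbind(w, seq_len(ncol(xc)))]
      out[s, ch, , ] <- array(xc[cbind(w, seq_len(ncol(xc)))],
                              dim = c(map$oh, map$ow))
    } else {
      out[s, ch, , ] <- array(colMeans(xc), dim = c(map$oh, map$ow))
    }
  }
  list(out = out, cache = list(map = map, xdim = d, argmax = amax))
}

poolBackward <- function(layer, cache, dout) {
  d <- cache$xdim; map <- cache$map
  dx <- array(0, dim = d)
  meanMode <- !identical(layer$method %||% "max", "max")
  kk <- nrow(map$idx)
  for (s in seq_len(d[1])) for (ch in seq_len(d[2])) {
    dy <- as.vector(dout[s, ch, , ])
    plane <- numeric(d[3] * d[4])
    if (meanMode) {
      acc <- rowsum(rep(dy / kk, each = kk), as.vector(map$idx))
      plane[as.integer(rownames(acc))] <- acc
    } else {
      tgt <- cache$argmax[s, ch, ]
      acc <- rowsum(dy, tgt)
      plane[as.integer(rownames(acc))] <- acc
    }
    dx[s, ch, , ] <- array(plane, dim = d[3:4])
  }
  list(dx = dx)
}

## Flatten a (n, c, h, w) batch to (n, c*h*w); column order is channel-
## fastest then row then column, matching R's native array order.
flattenBatch <- function(x) {
  if (length(dim(x)) == 2) return(x)
  matrix(as.vector(x), nrow = dim(x)[1])
}

linearForward <- function(layer, x) {
  xf <- flattenBatch(x)
  out <- xf %*% t(layer$weights)
  out <- sweep(out, 2, layer$bias, "+")
  list(out = out, cache = list(xf = xf, xdim = dim(x)))
}

linearBackward <- function(layer, cache, dout, needParams = FALSE) {
  dxf <- dout %*% layer$weights
  dx <- if (length(cache$xdim) > 2) array(dxf, dim = cache$xdim) else dxf
  list(dx = dx,
       dW = if (needParams) crossprod(dout, cache$xf),
       db = if (needParams) colSums(dout))
}

## Elementwise ablation: zero the selected channels/units of a layer output.
applyAblation <- function(out, abl) {
  d <- dim(out)
  if (identical(abl$channels, "all") &&
      (is.null(abl$units) || identical(abl$units, "all"))) {
    out[] <- 0
    return(out)
  }
  chsel <- if (identical(abl$channels, "all")) seq_len(d[2]) else abl$channels + 1L
  if (is.null(abl$units) || identical(abl$units, "all")) {
    if (length(d) == 2) out[, chsel] <- 0
    else out[, chsel, , ] <- 0
  } else {
    u <- abl$units
    for (i in seq_len(nrow(u))) {
      if (length(d) == 2) out[, chsel] <- 0
      else out[, chsel, u[i, 1] + 1L, u[i, 2] + 1L] <- 0
    }
  }
  out
}

#' Forward pass of a network
#'
#' Runs a stimulus batch through every layer in order, honouring any
#' ablation attached to the model, and optionally records intermediate
#' outputs and caches for the backward pass.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param x input batch: (n, channels, height, width) array for image models
#'   or an (n, features) matrix for vector models.
#' @param record character vector of layer names whose outputs to keep.
#' @param keepCache keep per-layer caches (internal; needed for gradients).
#' @param upTo stop after this layer (default: run the full network).
#' @return list with \code{output} (final or \code{upTo} layer output),
#'   \code{acts} (named list of recorded outputs) and, if requested,
#'   \code{caches}.
#' @export
networkForward <- function(model, x, record = character(), keepCache = FALSE,
                           upTo = NULL) {
  lnames <- names(model@layers)
  if (!is.null(upTo)) {
    if (!upTo %in% lnames)
      bindingError(sprintf("unknown layer '%s' (model has: %s)", upTo,
                           paste(lnames, collapse = ", ")))
    lnames <- lnames[seq_len(match(upTo, lnames))]
  }
  bad <- setdiff(record, names(model@layers))
  if (length(bad))
    bindingError(sprintf("unknown layer(s): %s", paste(bad, collapse = ", ")))
  if (is.matrix(x) || length(dim(x) %||% 1) == 2) x <- as.matrix(x)
  acts <- list(); caches <- list()
  cur <- x
  for (ln in lnames) {
    layer <- model@layers[[ln]]
    res <- switch(layer$kind,
      conv   = convForward(layer, cur),
      relu   = reluForward(layer, cur),
      pool   = poolForward(layer, cur),
      linear = linearForward(layer, cur))
    cur <- res$out
    if (ln %in% names(model@ablation))
      cur <- applyAblation(cur, model@ablation[[ln]])
    if (keepCache) caches[[ln]] <- res$cache
    if (ln %in% record) acts[[ln]] <- cur
  }
  list(output = cur, acts = acts, caches = if (keepCache) caches)
}

## Reverse pass from a seed gradient at `layer`'s output back to the input.
## Returns the input gradient and (optionally) per-layer parameter
## gradients. `guided` switches ReLU backward to guided backpropagation.
networkBackward <- function(model, caches, layer, seedGrad, guided = FALSE,
                            needParams = FALSE) {
  lnames <- names(model@layers)
  upto <- match(layer, lnames)
  if (is.na(upto)) bindingError(sprintf("unknown layer '%s'", layer))
  dout <- seedGrad
  pgrads <- list()
  for (i in rev(seq_len(upto))) {
    ln <- lnames[i]
    ly <- model@layers[[ln]]
    if (ln %in% names(model@ablation)) {
      z <- applyAblation(array(1, dim = dim(dout) %||% length(dout)),
                         model@ablation[[ln]])
      dout <- dout * z
    }
    res <- switch(ly$kind,
      conv   = convBackward(ly, caches[[ln]], dout, needParams),
      relu   = reluBackward(ly, caches[[ln]], dout, guided),
      pool   = poolBackward(ly, caches[[ln]], dout),
      linear = linearBackward(ly, caches[[ln]], dout, needParams))
    if (needParams && !is.null(res$dW))
      pgrads[[ln]] <- list(dW = res$dW, db = res$db)
    dout <- res$dx
  }
  list(dInput = dout, paramGrads = pgrads)
}

#' Output shape of every layer
#'
#' Walks the architecture from the model's input shape and returns each
#' layer's output shape: (channels, height, width) for spatial layers,
#' a single length for linear layers.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @return named list of integer shape vectors.
#' @export
layerShapes <- function(model) {
  shp <- model@inputShape
  out <- list()
  for (ln in names(model@layers)) {
    ly <- model@layers[[ln]]
    shp <- switch(ly$kind,
      conv = {
        d <- dim(ly$weights); st <- ly$stride %||% c(1L, 1L)
        pd <- ly$pad %||% c(0L, 0L)
        if (length(shp) != 3 || shp[1] != d[2])
          validationError(sprintf(
            "layer '%s': expects %d input channels, got shape [%s]",
            ln, d[2], paste(shp, collapse = " x ")))
        c(d[1], (shp[2] + 2 * pd[1] - d[3]) %/% st[1] + 1L,
          (shp[3] + 2 * pd[2] - d[4]) %/% st[2] + 1L)
      },
      relu = shp,
      pool = {
        sz <- ly$size %||% c(2L, 2L); st <- ly$stride %||% sz
        c(shp[1], (shp[2] - sz[1]) %/% st[1] + 1L,
          (shp[3] - sz[2]) %/% st[2] + 1L)
      },
      linear = {
        d <- dim(ly$weights)
        if (prod(shp) != d[2])
          validationError(sprintf(
            "layer '%s': expects %d inputs, got %d", ln, d[2], prod(shp)))
        d[1]
      })
    out[[ln]] <- as.integer(shp)
  }
  out
}

## Resolve a unit address (0-based) against a model; returns 1-based
## indices plus the layer's shape. `row`/`col` may be NULL for channel-level
## addressing or for 1-D layers.
bindUnit <- function(model, unit) {
  shp <- layerShapes(model)
  ln <- unit$layer
  if (is.null(ln) || !ln %in% names(shp))
    bindingError(sprintf("unknown layer '%s' (model has: %s)",
                         ln %||% "<missing>",
                         paste(names(shp), collapse = ", ")))
  s <- shp[[ln]]
  nchn <- s[1]
  ch <- unit$channel
  if (is.null(ch) || ch < 0 || ch >= nchn)
    bindingError(sprintf("channel %s out of range [0, %d) for layer '%s'",
                         ch %||% "<missing>", nchn, ln))
  spatial <- length(s) == 3
  row <- unit$row; col <- unit$col
  if (!is.null(row) || !is.null(col)) {
    if (!spatial) {
      if (!(identical(as.integer(row %||% 0L), 0L)))
        bindingError(sprintf("layer '%s' is 1-D; use (0, index) or channel-only addressing", ln))
      row <- NULL; col <- NULL
    } else {
      if (is.null(row) || is.null(col) ||
          row < 0 || row >= s[2] || col < 0 || col >= s[3])
        bindingError(sprintf(
          "unit (%s, %s) out of range [0, %d) x [0, %d) for layer '%s'",
          row %||% "?", col %||% "?", s[2], s[3], ln))
    }
  }
  list(layer = ln, ch = as.integer(ch) + 1L,
       row = if (!is.null(row)) as.integer(row) + 1L,
       col = if (!is.null(col)) as.integer(col) + 1L,
       shape = s, spatial = spatial)
}

## Scalar activation of a bound unit for each sample in a forward result.
## Channel-level addressing on spatial layers takes the spatial mean
## (the package-wide channel summarization convention).
unitActivation <- function(out, bu) {
  if (!bu$spatial) return(out[, bu$ch])
  if (is.null(bu$row)) {
    apply(out[, bu$ch, , , drop = FALSE], 1, mean)
  } else {
    out[, bu$ch, bu$row, bu$col]
  }
}

## Seed gradient (same shape as the layer output, single sample) selecting
## a unit or a channel's spatial mean.
unitSeedGradient <- function(outDim, bu) {
  g <- array(0, dim = outDim)
  if (!bu$spatial) {
    g[, bu$ch] <- 1
  } else if (is.null(bu$row)) {
    g[, bu$ch, , ] <- 1 / (outDim[3] * outDim[4])
  } else {
    g[, bu$ch, bu$row, bu$col] <- 1
  }
  g
}

#' Theoretical receptive field of a unit
#'
#' Computes, by walking the architecture, the input-pixel bounding box that
#' can influence a given unit: each convolution or pooling stage maps an
#' output index range back through its kernel, stride and padding. Serves
#' as the analytic counterpart of \code{\link{estimateEmpiricalRF}}.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param unit list(layer, channel, row, col), 0-based.
#' @return integer c(top, left, bottom, right), 0-based inclusive pixel
#'   coordinates; the full input for linear layers.
#' @export
theoreticalReceptiveField <- function(model, unit) {
  bu <- bindUnit(model, unit)
  lnames <- names(model@layers)
  upto <- match(bu$layer, lnames)
  inShape <- model@inputShape
  if (length(inShape) != 3)
    usageError("theoretical receptive fields require an image-input model")
  if (!bu$spatial || is.null(bu$row))
    return(c(0L, 0L, inShape[2] - 1L, inShape[3] - 1L))
  top <- bottom <- bu$row - 1L   # 0-based range at the target layer
  left <- right <- bu$col - 1L
  full <- FALSE
  for (i in rev(seq_len(upto))) {
    ly <- model@layers[[lnames[i]]]
    if (ly$kind == "linear") { full <- TRUE; break }
    if (ly$kind %in% c("conv", "pool")) {
      if (ly$kind == "conv") {
        k <- dim(ly$weights)[3:4]; st <- ly$stride %||% c(1L, 1L)
        pd <- ly$pad %||% c(0L, 0L)
      } else {
        k <- ly$size %||% c(2L, 2L); st <- ly$stride %||% k
        pd <- c(0L, 0L)
      }
      top <- top * st[1] - pd[1]; bottom <- bottom * st[1] - pd[1] + k[1] - 1L
      left <- left * st[2] - pd[2]; right <- right * st[2] - pd[2] + k[2] - 1L
    }
  }
  if (full) return(c(0L, 0L, inShape[2] - 1L, inShape[3] - 1L))
  as.integer(c(max(top, 0L), max(left, 0L),
               min(bottom, inShape[2] - 1L), min(right, inShape[3] - 1L)))
}
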