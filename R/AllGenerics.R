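#' Stimulus identifiers of an object
#' @param x an object carrying stimulus IDs.
#' @return character vector of stimulus IDs.
#' @export
setGeneric("stimIds", function(x) standardGeneric("stimIds"))

#' @rdname stimIds
#' @export
setMethod("stimIds", "StimulusTable", function(x) x@data$stim_id)
#' @rdname stimIds
#' @export
setMethod("stimIds", "ActivationStore", function(x) x@stimIds)
#' @rdname stimIds
#' @export
setMethod("stimIds", "ResponseMatrix", function(x) x@stimIds)
#' @rdname stimIds
#' @export
setMethod("stimIds", "RDM", function(x) x@stimIds)

#' Site identifiers of a ResponseMatrix
#' @param x a \linkS4class{ResponseMatrix}.
#' @return character vector of site IDs.
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
#' @rdname siteIds
#' @export
setMethod("siteIds", "ResponseMatrix", function(x) x@siteIds)

#' Layer names of an object
#' @param x a \linkS4class{NetworkModel}, \linkS4class{ActivationStore} or
#'   \linkS4class{MaskSpec}.
#' @return character vector of layer names, in order.
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname layerNames
#' @export
setMethod("layerNames", "NetworkModel", function(x) names(x@layers))
#' @rdname layerNames
#' @export
setMethod("layerNames", "ActivationStore", function(x) names(x@layers))
#' @rdname layerNames
#' @export
setMethod("layerNames", "MaskSpec", function(x) names(x@entries))

#' Numeric payload of an object
#' @param x a \linkS4class{ResponseMatrix}, \linkS4class{RDM},
#'   \linkS4class{SaliencyMap} or \linkS4class{RFEstimate}.
#' @return the object's numeric matrix/array.
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname values
#' @export
setMethod("values", "ResponseMatrix", function(x) {
  v <- x@values; dimnames(v) <- list(x@stimIds, x@siteIds); v
})
#' @rdname values
#' @export
setMethod("values", "RDM", function(x) {
  v <- x@values; dimnames(v) <- list(x@stimIds, x@stimIds); v
})
#' @rdname values
#' @export
setMethod("values", "SaliencyMap", function(x) x@values)
#' @rdname values
#' @export
setMethod("values", "RFEstimate", function(x) x@deltaMap)

#' Activation tensor of one layer in a store
#' @param x an \linkS4class{ActivationStore}.
#' @param layer layer name.
#' @return numeric array, first axis = stimuli.
#' @export
setGeneric("activation", function(x, layer) standardGeneric("activation"))
#' @rdname activation
#' @export
setMethod("activation", "ActivationStore", function(x, layer) {
  if (!layer %in% names(x@layers))
    bindingError(sprintf("layer '%s' not present in store (has: %s)",
                         layer, paste(names(x@layers), collapse = ", ")))
  x@layers[[layer]]
})

#' Mask entries of a MaskSpec
#' @param x a \linkS4class{MaskSpec}.
#' @return named list of per-layer selections.
#' @export
maskEntries <- function(x) x@entries

#' Folds of a CVScheme
#' @param x a \linkS4class{CVScheme}.
#' @return list of held-out index vectors.
#' @export
cvFolds <- function(x) x@folds

#' Per-site scores of an EncodingResult
#' @param x an \linkS4class{EncodingResult}.
#' @return data.frame with site_id, pearson_r, explained_variance.
#' @export
encodingScores <- function(x) x@scores

## ---- show methods ---------------------------------------------------------

setMethod("show", "StimulusTable", function(object) {
  cat(sprintf("StimulusTable: %d stimuli (%s), dir='%s'\n",
              nrow(object@data), object@stimType, object@stimDir))
  attrs <- setdiff(names(object@data), c("stim_id", "onset", "duration"))
  if (length(attrs)) cat("  attributes:", paste(attrs, collapse = ", "), "\n")
})

setMethod("show", "MaskSpec", function(object) {
  cat(sprintf("MaskSpec over %d layer(s):\n", length(object@entries)))
  for (ln in names(object@entries)) {
    e <- object@entries[[ln]]
    ch <- if (identical(e$channels, "all")) "all"
          else paste(e$channels, collapse = ",")
    un <- if (identical(e$units, "all")) "all"
          else paste(apply(e$units, 1, paste, collapse = ":"), collapse = ";")
    cat(sprintf("  %s: channels=%s units=%s\n", ln, ch, un))
  }
})

setMethod("show", "ActivationStore", function(object) {
  cat(sprintf("ActivationStore: %d stimuli, %d layer(s)\n",
              length(object@stimIds), length(object@layers)))
  for (ln in names(object@layers))
    cat(sprintf("  %s: [%s]\n", ln,
                paste(dim(object@layers[[ln]]), collapse = " x ")))
})

setMethod("show", "ResponseMatrix", function(object) {
  nNaN <- sum(colSums(is.na(object@values)) > 0)
  cat(sprintf("ResponseMatrix: %d stimuli x %d sites%s\n",
              length(object@stimIds), length(object@siteIds),
              if (nNaN) sprintf(" (%d sites contain NaN)", nNaN) else ""))
})

setMethod("show", "RDM", function(object) {
  cat(sprintf("RDM (%s distance): %d x %d stimuli\n", object@metric,
              length(object@stimIds), length(object@stimIds)))
})

setMethod("show", "NetworkModel", function(object) {
  cat(sprintf("NetworkModel '%s', input [%s]\n", object@name,
              paste(object@inputShape, collapse = " x ")))
  shp <- layerShapes(object)
  for (ln in names(object@layers)) {
    abl <- if (ln %in% names(object@ablation)) "  [ablated]" else ""
    cat(sprintf("  %s (%s) -> [%s]%s\n", ln, object@layers[[ln]]$kind,
                paste(shp[[ln]], collapse = " x "), abl))
  }
})

setMethod("show", "CVScheme", function(object) {
  cat(sprintf("CVScheme: %s, %d fold(s) over %d samples (seed %d)\n",
              object@kind, length(object@folds), object@n, object@seed))
})

setMethod("show", "EncodingResult", function(object) {
  cat(sprintf("EncodingResult (%s): %d site(s), %d excluded\n",
              object@family, nrow(object@scores), length(object@excludedSites)))
  if (nrow(object@scores))
    cat(sprintf("  median pooled pearson_r = %.3f\n",
                stats::median(object@scores$pearson_r, na.rm = TRUE)))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult (%s): %s = %.4f over %d folds\n", object@family,
              object@scoreMetric, object@score, length(object@perFoldScores)))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: observed = %.4f, p = %.4g (%d permutations)\n",
              object@observed, object@pValue, length(object@nullSamples)))
})

setMethod("show", "RFEstimate", function(object) {
  if (object@empty) {
    cat("RFEstimate: empty (occlusion never changed the response)\n")
  } else {
    cat(sprintf("RFEstimate: extent (top=%d, left=%d, bottom=%d, right=%d)\n",
                object@extent[1], object@extent[2], object@extent[3],
                object@extent[4]))
  }
})

setMethod("show", "SynthesisResult", function(object) {
  n <- length(object@trajectory)
  cat(sprintf("SynthesisResult: %d iterations, activation %.4f -> %.4f\n",
              n - 1, object@trajectory[1], object@trajectory[n]))
})
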