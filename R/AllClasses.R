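#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers.
##
## Indexing convention: channel indices and unit (row, col) coordinates are
## 0-based everywhere -- in mask files, in the API, and in reported results.
## This matches the convention of the deep-learning ecosystem these objects
## describe and is used consistently across the package.
## ---------------------------------------------------------------------------

#' StimulusTable: an ordered stimulus listing with attributes
#'
#' Holds the stimulus metadata read from (or written to) a stimulus CSV file:
#' a root directory, a stimulus type, and one ordered row per stimulus with a
#' unique \code{stim_id}, optional \code{onset}/\code{duration} (seconds) and
#' arbitrary per-stimulus attribute columns (labels, conditions, ...). Row
#' order is meaningful and preserved through all I/O.
#'
#' @slot stimDir root directory for relative stimulus paths.
#' @slot stimType one of \code{"image"}, \code{"audio"}, \code{"video"}.
#' @slot data data.frame with column \code{stim_id} plus optional
#'   \code{onset}, \code{duration} and attribute columns.
#' @exportClass StimulusTable
setClass("StimulusTable",
  slots = c(stimDir = "character", stimType = "character", data = "data.frame"))

setValidity("StimulusTable", function(object) {
  if (!object@stimType %in% c("image", "audio", "video"))
    return(sprintf("unknown stimulus type '%s'", object@stimType))
  if (!"stim_id" %in% names(object@data))
    return("data must contain a 'stim_id' column")
  ids <- object@data$stim_id
  if (anyDuplicated(ids))
    return(sprintf("duplicate stim_id values: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (cl in c("onset", "duration")) {
    if (cl %in% names(object@data)) {
      v <- object@data[[cl]]
      if (!is.numeric(v)) return(sprintf("'%s' must be numeric", cl))
      if (any(v < 0, na.rm = TRUE)) return(sprintf("'%s' must be >= 0", cl))
    }
  }
  TRUE
})

#' Construct a StimulusTable
#'
#' @param data data.frame with a \code{stim_id} column plus optional
#'   \code{onset}, \code{duration} and attribute columns.
#' @param stimDir root directory for stimulus files.
#' @param stimType stimulus modality: "image", "audio" or "video".
#' @return a \linkS4class{StimulusTable}.
#' @export
StimulusTable <- function(data, stimDir = ".", stimType = "image") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  rownames(data) <- NULL
  if ("stim_id" %in% names(data)) data$stim_id <- as.character(data$stim_id)
  new("StimulusTable", stimDir = stimDir, stimType = stimType, data = data)
}

#' MaskSpec: a selection of layers, channels and units of a network
#'
#' Each entry names one layer together with the channels and spatial units of
#' interest. Channels are 0-based indices or \code{"all"}; units are 0-based
#' (row, col) coordinates within a channel's spatial map or \code{"all"}.
#' Whether the addresses exist in a concrete network is checked when the mask
#' is bound to a model, not at construction.
#'
#' @slot entries named list (one element per layer) of
#'   \code{list(channels = integer|"all", units = 2-col matrix|"all")}.
#' @exportClass MaskSpec
setClass("MaskSpec", slots = c(entries = "list"))

setValidity("MaskSpec", function(object) {
  if (length(object@entries) == 0) return("a mask must name at least one layer")
  nm <- names(object@entries)
  if (is.null(nm) || any(nm == "")) return("mask entries must be named by layer")
  if (anyDuplicated(nm))
    return(sprintf("layer listed more than once: %s",
                   paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  for (e in object@entries) {
    ch <- e$channels
    if (!(identical(ch, "all") ||
          (is.numeric(ch) && all(ch == floor(ch)) && all(ch >= 0))))
      return("channels must be 'all' or non-negative integers")
    un <- e$units
    if (!(identical(un, "all") ||
          (is.matrix(un) && ncol(un) == 2 && all(un == floor(un)) && all(un >= 0))))
      return("units must be 'all' or a 2-column matrix of non-negative (row, col)")
  }
  TRUE
})

#' Construct a MaskSpec
#'
#' @param ... named arguments, one per layer; each is either \code{"all"}
#'   (all channels, all units), a vector of 0-based channel indices, or a
#'   list with elements \code{channels} and/or \code{units}.
#' @return a \linkS4class{MaskSpec}.
#' @examples
#' MaskSpec(conv1 = c(0, 2), fc1 = "all")
#' @export
MaskSpec <- function(...) {
  args <- list(...)
  entries <- lapply(args, function(a) {
    if (identical(a, "all")) return(list(channels = "all", units = "all"))
    if (is.numeric(a)) return(list(channels = as.integer(a), units = "all"))
    list(channels = if (identical(a$channels %||% "all", "all")) "all"
                    else as.integer(a$channels),
         units = if (identical(a$units %||% "all", "all")) "all"
                 else {
                   u <- a$units
                   if (!is.matrix(u)) u <- matrix(as.integer(u), ncol = 2, byrow = TRUE)
                   storage.mode(u) <- "integer"
                   u
                 })
  })
  new("MaskSpec", entries = entries)
}

#' ActivationStore: per-layer activation tensors for a stimulus set
#'
#' The result of scanning a network: for every masked layer a numeric array
#' of shape (n_stim, n_chn, d1, d2, ...) -- or (n_stim, n_chn) for 1-D
#' layers -- whose first axis follows the stimulus order of the table used
#' at extraction, plus provenance metadata.
#'
#' @slot layers named list of numeric arrays, first axis = stimuli.
#' @slot stimIds character vector of stimulus IDs (first-axis labels).
#' @slot provenance list with elements such as \code{model}, \code{mask},
#'   \code{created}.
#' @exportClass ActivationStore
setClass("ActivationStore",
  slots = c(layers = "list", stimIds = "character", provenance = "list"))

setValidity("ActivationStore", function(object) {
  if (length(object@layers) == 0) return("store must contain at least one layer")
  nm <- names(object@layers)
  if (is.null(nm) || any(nm == "")) return("layer tensors must be named")
  n <- length(object@stimIds)
  for (ln in nm) {
    d <- dim(object@layers[[ln]]) %||% length(object@layers[[ln]])
    if (d[1] != n)
      return(sprintf("layer '%s': first axis (%d) != number of stim_ids (%d)",
                     ln, d[1], n))
  }
  TRUE
})

#' Construct an ActivationStore
#' @param layers named list of arrays (first axis = stimuli).
#' @param stimIds character stimulus IDs.
#' @param provenance optional metadata list.
#' @return an \linkS4class{ActivationStore}.
#' @export
ActivationStore <- function(layers, stimIds, provenance = list()) {
  new("ActivationStore", layers = layers, stimIds = as.character(stimIds),
      provenance = provenance)
}

#' ResponseMatrix: measured responses, stimuli by measurement sites
#'
#' The "brain side" of every mapping analysis: a real n_stim x n_sites
#' matrix (e.g. image-evoked BOLD amplitudes per voxel) with explicit
#' stimulus and site identifiers. NaN entries are allowed and flag censored
#' sites; model fitting excludes such sites and reports them rather than
#' erroring. Alignment to other objects is always by \code{stim_id}, never
#' by silent reordering.
#'
#' @slot values numeric matrix (n_stim x n_sites).
#' @slot siteIds character site identifiers (columns).
#' @slot stimIds character stimulus identifiers (rows).
#' @exportClass ResponseMatrix
setClass("ResponseMatrix",
  slots = c(values = "matrix", siteIds = "character", stimIds = "character"))

setValidity("ResponseMatrix", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (nrow(object@values) != length(object@stimIds))
    return("values must have one row per stim_id")
  if (ncol(object@values) != length(object@siteIds))
    return("values must have one column per site_id")
  if (anyDuplicated(object@stimIds)) return("duplicate stim_ids")
  TRUE
})

#' Construct a ResponseMatrix
#' @param values numeric matrix, stimuli in rows, sites in columns.
#' @param stimIds,siteIds row/column identifiers; defaults taken from
#'   dimnames when present.
#' @return a \linkS4class{ResponseMatrix}.
#' @export
ResponseMatrix <- function(values, stimIds = rownames(values),
                           siteIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(stimIds)) stimIds <- sprintf("stim%03d", seq_len(nrow(values)))
  if (is.null(siteIds)) siteIds <- sprintf("site%03d", seq_len(ncol(values)))
  dimnames(values) <- NULL
  new("ResponseMatrix", values = values, stimIds = as.character(stimIds),
      siteIds = as.character(siteIds))
}

#' RDM: representational dissimilarity matrix
#'
#' A symmetric n_stim x n_stim matrix of pairwise pattern dissimilarities
#' with a zero diagonal, characterizing the representational geometry of one
#' system (a network layer or a set of measurement sites) over a stimulus
#' set. Euclidean entries are >= 0; correlation-distance entries lie in
#' [0, 2].
#'
#' @slot values symmetric numeric matrix, zero diagonal.
#' @slot metric "euclidean" or "correlation".
#' @slot stimIds character stimulus identifiers.
#' @exportClass RDM
setClass("RDM",
  slots = c(values = "matrix", metric = "character", stimIds = "character"))

setValidity("RDM", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("RDM must be square")
  if (nrow(v) != length(object@stimIds)) return("stimIds length != matrix size")
  if (!isTRUE(all.equal(v, t(v), tolerance = 0)) && !identical(v, t(v)))
    return("RDM must be exactly symmetric")
  if (any(diag(v) != 0)) return("RDM diagonal must be zero")
  if (!object@metric %in% c("euclidean", "correlation"))
    return(sprintf("unknown metric '%s'", object@metric))
  if (object@metric == "euclidean" && any(v < 0)) return("euclidean entries must be >= 0")
  if (object@metric == "correlation" && (any(v < 0) || any(v > 2)))
    return("correlation-distance entries must lie in [0, 2]")
  TRUE
})

#' NetworkModel: a layered feed-forward network
#'
#' A deterministic sequential network: an ordered list of named layers
#' (conv, relu, pool, linear) with explicit weights, supporting a forward
#' pass, reverse-mode gradients with respect to inputs and parameters, and
#' channel/unit ablation. Layer names are unique and stable; requesting an
#' unknown layer is an error, never a silent skip.
#'
#' @slot name model name (provenance).
#' @slot inputShape integer input shape, (channels, height, width) for image
#'   models or a single feature count for vector models.
#' @slot layers named ordered list of layer descriptors.
#' @slot ablation named list layer -> list(channels, units) zeroed at that
#'   layer's output.
#' @exportClass NetworkModel
setClass("NetworkModel",
  slots = c(name = "character", inputShape = "integer", layers = "list",
            ablation = "list"))

setValidity("NetworkModel", function(object) {
  nm <- names(object@layers)
  if (length(object@layers) == 0) return("model needs at least one layer")
  if (is.null(nm) || anyDuplicated(nm)) return("layer names must be unique")
  kinds <- vapply(object@layers, function(l) l$kind, character(1))
  if (!all(kinds %in% c("conv", "relu", "pool", "linear")))
    return("layer kind must be conv, relu, pool or linear")
  TRUE
})

#' CVScheme: a cross-validation fold assignment
#'
#' @slot kind "kfold" or "loo".
#' @slot k number of folds.
#' @slot seed RNG seed that produced the assignment.
#' @slot n number of samples.
#' @slot folds list of disjoint held-out index vectors covering 1..n.
#' @exportClass CVScheme
setClass("CVScheme",
  slots = c(kind = "character", k = "integer", seed = "integer",
            n = "integer", folds = "list"))

setValidity("CVScheme", function(object) {
  idx <- sort(unlist(object@folds))
  if (!identical(idx, seq_len(object@n)))
    return("folds must be disjoint and cover all samples")
  sizes <- lengths(object@folds)
  if (object@kind == "kfold" && diff(range(sizes)) > 1)
    return("kfold fold sizes may differ by at most 1")
  if (object@kind == "loo" && any(sizes != 1))
    return("loo folds must be singletons")
  TRUE
})

#' EncodingResult: a fitted, cross-validated encoding model
#'
#' @slot family model family ("glm", "ridge", "lasso" or "pls").
#' @slot scores data.frame with columns \code{site_id}, \code{pearson_r},
#'   \code{explained_variance} from pooled held-out predictions.
#' @slot weights feature x site matrix from the final whole-data fit.
#' @slot intercepts per-site intercepts of the final fit.
#' @slot pooledPredictions n_stim x n_sites matrix of held-out predictions.
#' @slot excludedSites sites dropped for NaN or zero variance.
#' @slot cv the \linkS4class{CVScheme} used.
#' @slot metadata list (standardization mode, penalty, components, ...).
#' @exportClass EncodingResult
setClass("EncodingResult",
  slots = c(family = "character", scores = "data.frame", weights = "matrix",
            intercepts = "numeric", pooledPredictions = "matrix",
            excludedSites = "character", cv = "CVScheme", metadata = "list"))

#' DecodingResult: a fitted, cross-validated decoding model
#'
#' @slot family "logistic", "glm", "ridge" or "lasso".
#' @slot score pooled held-out score.
#' @slot scoreMetric "accuracy", "pearson_r" or "explained_variance".
#' @slot perFoldScores score computed within each held-out fold.
#' @slot pooledPredictions held-out predictions in stimulus order.
#' @slot weights decoding weights (response space) from the final fit.
#' @slot cv the \linkS4class{CVScheme} used.
#' @slot metadata list.
#' @exportClass DecodingResult
setClass("DecodingResult",
  slots = c(family = "character", score = "numeric", scoreMetric = "character",
            perFoldScores = "numeric", pooledPredictions = "ANY",
            weights = "numeric", cv = "CVScheme", metadata = "list"))

#' PermutationResult: observed statistic against a permutation null
#'
#' The p-value uses the add-one convention
#' p = (1 + #\{null >= observed\}) / (1 + n_perm), which is always in (0, 1].
#'
#' @slot observed observed statistic.
#' @slot nullSamples vector of length n_perm.
#' @slot pValue one-sided (greater) permutation p-value.
#' @slot seed RNG seed.
#' @exportClass PermutationResult
setClass("PermutationResult",
  slots = c(observed = "numeric", nullSamples = "numeric", pValue = "numeric",
            seed = "integer"))

#' SaliencyMap: input-gradient of a unit's activation
#'
#' @slot values numeric array with the probed stimulus's shape.
#' @slot unit list(layer, channel[, row, col]); channel-level maps
#'   differentiate the channel's spatial-mean activation.
#' @slot method "vanilla" or "guided".
#' @exportClass SaliencyMap
setClass("SaliencyMap",
  slots = c(values = "array", unit = "list", method = "character"))

#' SynthesisResult: an optimal stimulus synthesized by gradient ascent
#'
#' @slot stimulus synthesized input tensor.
#' @slot trajectory target activation per iteration (length n_iter + 1,
#'   including the initial noise).
#' @slot config list(n_iter, step_size, l2_decay, blur_sigma, blur_every,
#'   seed) actually used.
#' @exportClass SynthesisResult
setClass("SynthesisResult",
  slots = c(stimulus = "array", trajectory = "numeric", config = "list"))

#' RFEstimate: occlusion-estimated empirical receptive field of a unit
#'
#' @slot unit list(layer, channel, row, col).
#' @slot extent pixel bounding box c(top, left, bottom, right), 0-based
#'   inclusive; NA when empty.
#' @slot empty TRUE when occlusion never changed the unit's response.
#' @slot deltaMap |response change| per occluder position.
#' @exportClass RFEstimate
setClass("RFEstimate",
  slots = c(unit = "list", extent = "integer", empty = "logical",
            deltaMap = "matrix"))

#' GroundTruth: generative parameters of a synthetic linkage
#'
#' @slot weights feature -> site linkage weight matrix.
#' @slot noiseSd response noise standard deviation.
#' @slot labelRule description of how labels derive from features.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(weights = "matrix", noiseSd = "numeric", labelRule = "character"))
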