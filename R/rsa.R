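## ---------------------------------------------------------------------------
## Representational similarity analysis.
## ---------------------------------------------------------------------------

#' Compute a representational dissimilarity matrix
#'
#' Pairwise dissimilarity of the rows of a stimulus-by-feature pattern
#' matrix: \code{"euclidean"} is the L2 distance, \code{"correlation"} is
#' 1 - Pearson r across the feature axis (entries in [0, 2]). The result is
#' exactly symmetric with a zero diagonal.
#'
#' @param patterns numeric matrix (n_stim x n_feat), n_stim >= 2; the
#'   correlation metric additionally requires n_feat >= 2 and no constant
#'   rows.
#' @param metric "euclidean" or "correlation".
#' @param stimIds optional stimulus IDs (default: rownames or stim001...).
#' @return an \linkS4class{RDM}.
#' @export
computeRDM <- function(patterns, metric = c("euclidean", "correlation"),
                       stimIds = NULL) {
  metric <- match.arg(metric)
  patterns <- as.matrix(patterns)
  n <- nrow(patterns)
  if (n < 2) usageError("need at least 2 stimuli")
  stimIds <- stimIds %||% rownames(patterns) %||% sprintf("stim%03d", seq_len(n))
  if (metric == "euclidean") {
    v <- as.matrix(stats::dist(patterns, method = "euclidean"))
  } else {
    if (ncol(patterns) < 2)
      usageError("correlation distance requires at least 2 features")
    sds <- apply(patterns, 1, stats::sd)
    if (any(sds == 0))
      validationError(sprintf(
        "constant pattern row(s) under correlation metric: %s",
        paste(stimIds[sds == 0], collapse = ", ")))
    v <- 1 - stats::cor(t(patterns))
    v <- pmin(pmax(v, 0), 2)
  }
  v[lower.tri(v)] <- t(v)[lower.tri(v)]  # enforce exact symmetry
  diag(v) <- 0
  dimnames(v) <- NULL
  new("RDM", values = v, metric = metric, stimIds = as.character(stimIds))
}

#' Vectorize an RDM
#'
#' Strict upper triangle in row-major order: for stimuli 1..n the entries
#' (1,2), (1,3), ..., (1,n), (2,3), ... of the dissimilarity matrix.
#'
#' @param rdm an \linkS4class{RDM} or a symmetric matrix.
#' @return numeric vector of length n(n-1)/2.
#' @export
vectorizeRDM <- function(rdm) {
  v <- if (is(rdm, "RDM")) rdm@values else as.matrix(rdm)
  if (!identical(dim(v)[1], dim(v)[2]) || !isTRUE(all.equal(v, t(v))))
    validationError("input must be a symmetric matrix")
  tv <- t(v)
  tv[lower.tri(tv)]
}

#' Compare two RDMs
#'
#' Correlation between the vectorized upper triangles of two RDMs over the
#' same stimuli, in the same order (mismatched stimulus IDs are an error --
#' there is no silent reordering). Kendall's tau is the tie-corrected
#' tau-b.
#'
#' @param rdmA,rdmB \linkS4class{RDM} objects with identical stim_id order.
#' @param method "pearson", "spearman" or "kendall".
#' @return the correlation (symmetric in its arguments).
#' @export
compareRDMs <- function(rdmA, rdmB, method = c("pearson", "spearman",
                                               "kendall")) {
  method <- match.arg(method)
  if (!identical(rdmA@stimIds, rdmB@stimIds))
    alignmentError("RDMs are over different stimuli or a different order")
  stats::cor(vectorizeRDM(rdmA), vectorizeRDM(rdmB), method = method)
}

#' Permutation test of representational similarity
#'
#' Observed statistic: \code{compareRDMs(rdmA, rdmB, method)}. Null
#' distribution: the stimulus labels of \code{rdmB} are randomly permuted
#' (rows and columns jointly -- equivalent to relabeling the stimuli) and
#' the comparison recomputed \code{nPerm} times. Because the comparison is
#' symmetric in its arguments, permuting either RDM yields the same null.
#' The p-value uses the add-one convention (one-sided, greater).
#'
#' @param rdmA,rdmB \linkS4class{RDM} objects with identical stim_id order.
#' @param method correlation method as in \code{\link{compareRDMs}}.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return a \linkS4class{PermutationResult}.
#' @export
rdmPermutationTest <- function(rdmA, rdmB, method = "pearson", nPerm = 1000L,
                               seed = 0L) {
  if (nPerm < 1) usageError("nPerm must be >= 1")
  observed <- compareRDMs(rdmA, rdmB, method)
  va <- vectorizeRDM(rdmA)
  vb <- rdmB@values
  n <- length(rdmB@stimIds)
  nulls <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    p <- sample.int(n)
    stats::cor(va, vectorizeRDM(vb[p, p]), method = method)
  }, numeric(1)))
  new("PermutationResult", observed = observed, nullSamples = nulls,
      pValue = (1 + sum(nulls >= observed)) / (1 + nPerm),
      seed = as.integer(seed))
}

#' Average patterns by a stimulus condition
#'
#' Pre-step for condition-averaged RDMs: averages the pattern rows of each
#' condition (in order of first appearance) so an RDM can be computed over
#' conditions instead of single stimuli.
#'
#' @param patterns numeric matrix (n_stim x n_feat).
#' @param conditions vector of condition labels, length n_stim.
#' @return matrix with one row per condition, rownames = condition labels.
#' @export
conditionAverage <- function(patterns, conditions) {
  patterns <- as.matrix(patterns)
  if (length(conditions) != nrow(patterns))
    alignmentError("conditions must have one entry per pattern row")
  lev <- unique(as.character(conditions))
  out <- t(vapply(lev, function(l)
    colMeans(patterns[as.character(conditions) == l, , drop = FALSE]),
    numeric(ncol(patterns))))
  rownames(out) <- lev
  out
}
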