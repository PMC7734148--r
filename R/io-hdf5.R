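## ---------------------------------------------------------------------------
## HDF5 formats (via rhdf5).
##
## Activation file layout: one group per layer, named exactly by the layer
## name, with a float32 dataset "activation"; a root-level string dataset
## "stim_ids"; root attributes "model", "created", "mask".
## ---------------------------------------------------------------------------

h5Recreate <- function(path) {
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) ioError(sprintf("cannot create HDF5 file '%s'", path))
  invisible(NULL)
}

h5TryRead <- function(path, name) {
  tryCatch(rhdf5::h5read(path, name),
           error = function(e)
             ioError(sprintf("cannot read '%s' from '%s': %s", name, path,
                             conditionMessage(e))))
}

#' Write an activation store to HDF5
#'
#' One group per layer holding a float32 dataset \code{activation};
#' stimulus IDs as a root dataset; model name, mask summary and creation
#' time as root attributes. Values already representable in float32 survive
#' a read/write roundtrip bit-exactly.
#'
#' @param store an \linkS4class{ActivationStore}.
#' @param path destination path.
#' @export
writeActivationStore <- function(store, path) {
  validObject(store)  # first-axis/stim_ids mismatch fails before any write
  h5Recreate(path)
  on.exit(rhdf5::h5closeAll())
  for (ln in names(store@layers)) {
    a <- store@layers[[ln]]
    rhdf5::h5createGroup(path, ln)
    rhdf5::h5createDataset(path, paste0(ln, "/activation"), dims = dim(a),
                           H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(a, path, paste0(ln, "/activation"))
  }
  rhdf5::h5write(store@stimIds, path, "stim_ids")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(store@provenance$model %||% "", fid, "model")
  rhdf5::h5writeAttribute(store@provenance$mask %||% "", fid, "mask")
  rhdf5::h5writeAttribute(store@provenance$created %||%
                            format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                          fid, "created")
  rhdf5::H5Fclose(fid)
  invisible(NULL)
}

#' Read an activation store from HDF5
#'
#' Inverse of \code{\link{writeActivationStore}}. Errors (missing stim_ids,
#' no layer groups, corrupt file) never return a partial object.
#'
#' @param path file path.
#' @return an \linkS4class{ActivationStore}.
#' @export
readActivationStore <- function(path) {
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  ls <- tryCatch(rhdf5::h5ls(path),
                 error = function(e)
                   ioError(sprintf("not a readable HDF5 file: %s", path)))
  on.exit(rhdf5::h5closeAll())
  groups <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  if (!"stim_ids" %in% ls$name[ls$group == "/"])
    formatError("activation file lacks 'stim_ids'")
  if (length(groups) == 0) formatError("activation file contains no layers")
  ids <- as.character(h5TryRead(path, "stim_ids"))
  layers <- list()
  for (g in groups)
    layers[[g]] <- h5TryRead(path, paste0(g, "/activation"))
  at <- rhdf5::h5readAttributes(path, "/")
  ActivationStore(layers, ids,
                  provenance = list(model = as.character(at$model %||% ""),
                                    mask = as.character(at$mask %||% ""),
                                    created = as.character(at$created %||% "")))
}

#' Write an RDM to HDF5
#'
#' Uses the activation-file dialect: group \code{rdm}, dataset
#' \code{values}, root datasets \code{stim_ids}, attribute \code{metric}.
#'
#' @param rdm an \linkS4class{RDM}.
#' @param path destination path.
#' @export
writeRDM <- function(rdm, path) {
  validObject(rdm)
  h5Recreate(path)
  on.exit(rhdf5::h5closeAll())
  rhdf5::h5createGroup(path, "rdm")
  rhdf5::h5write(rdm@values, path, "rdm/values")
  rhdf5::h5write(rdm@stimIds, path, "stim_ids")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(rdm@metric, fid, "metric")
  rhdf5::H5Fclose(fid)
  invisible(NULL)
}

#' Read an RDM from HDF5
#' @param path file path.
#' @return an \linkS4class{RDM}.
#' @export
readRDM <- function(path) {
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  on.exit(rhdf5::h5closeAll())
  v <- h5TryRead(path, "rdm/values")
  ids <- as.character(h5TryRead(path, "stim_ids"))
  at <- rhdf5::h5readAttributes(path, "/")
  new("RDM", values = v, metric = as.character(at$metric %||% "euclidean"),
      stimIds = ids)
}

## ---- network serialization: HDF5 weights + JSON architecture sidecar ------

#' Save a network as an HDF5 weight file with a JSON architecture sidecar
#'
#' Writes \code{<prefix>.json} (name, input shape, ordered layer
#' descriptors without weights) and \code{<prefix>.h5} (one group per
#' parameterized layer with float64 datasets \code{weights}/\code{bias}).
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param prefix path prefix (without extension).
#' @export
saveNetwork <- function(model, prefix) {
  arch <- lapply(names(model@layers), function(ln) {
    ly <- model@layers[[ln]]
    d <- switch(ly$kind,
      conv = list(kind = "conv", kernel = dim(ly$weights)[3:4],
                  out = dim(ly$weights)[1],
                  stride = ly$stride %||% c(1L, 1L),
                  pad = ly$pad %||% c(0L, 0L)),
      pool = list(kind = "pool", method = ly$method %||% "max",
                  size = ly$size %||% c(2L, 2L),
                  stride = ly$stride %||% ly$size %||% c(2L, 2L)),
      linear = list(kind = "linear", out = dim(ly$weights)[1]),
      list(kind = ly$kind))
    c(list(name = ln), d)
  })
  abl <- lapply(model@ablation, function(a) list(
    channels = if (identical(a$channels, "all")) "all" else as.integer(a$channels),
    units = if (identical(a$units %||% "all", "all")) "all"
            else apply(a$units, 1, paste, collapse = ":")))
  jsonlite::write_json(
    list(name = model@name, input_shape = model@inputShape, layers = arch,
         ablation = abl),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  h5path <- paste0(prefix, ".h5")
  h5Recreate(h5path)
  on.exit(rhdf5::h5closeAll())
  for (ln in names(model@layers)) {
    ly <- model@layers[[ln]]
    if (!ly$kind %in% c("conv", "linear")) next
    rhdf5::h5createGroup(h5path, ln)
    rhdf5::h5write(ly$weights, h5path, paste0(ln, "/weights"))
    rhdf5::h5write(ly$bias, h5path, paste0(ln, "/bias"))
  }
  invisible(NULL)
}

#' Load a network saved by \code{\link{saveNetwork}}
#' @param prefix path prefix (without extension).
#' @return a \linkS4class{NetworkModel}.
#' @export
loadNetwork <- function(prefix) {
  jpath <- paste0(prefix, ".json"); h5path <- paste0(prefix, ".h5")
  if (!file.exists(jpath)) ioError(sprintf("no such file: %s", jpath))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  on.exit(rhdf5::h5closeAll())
  layers <- list()
  archs <- if (is.data.frame(meta$layers))
    split(meta$layers, seq_len(nrow(meta$layers))) else meta$layers
  for (a in archs) {
    a <- as.list(a)
    ln <- as.character(a$name)
    ly <- switch(as.character(a$kind),
      conv = list(kind = "conv",
                  weights = h5TryRead(h5path, paste0(ln, "/weights")),
                  bias = as.numeric(h5TryRead(h5path, paste0(ln, "/bias"))),
                  stride = as.integer(unlist(a$stride)),
                  pad = as.integer(unlist(a$pad))),
      linear = list(kind = "linear",
                    weights = as.matrix(h5TryRead(h5path, paste0(ln, "/weights"))),
                    bias = as.numeric(h5TryRead(h5path, paste0(ln, "/bias")))),
      pool = list(kind = "pool", method = as.character(a$method),
                  size = as.integer(unlist(a$size)),
                  stride = as.integer(unlist(a$stride))),
      relu = list(kind = "relu"))
    layers[[ln]] <- ly
  }
  abl <- list()
  for (ln in names(meta$ablation %||% list())) {
    a <- meta$ablation[[ln]]
    abl[[ln]] <- list(
      channels = if (identical(a$channels, "all")) "all"
                 else as.integer(unlist(a$channels)),
      units = if (identical(a$units, "all")) "all"
              else {
                m <- t(vapply(strsplit(unlist(a$units), ":"), as.integer,
                              integer(2)))
                storage.mode(m) <- "integer"; m
              })
  }
  new("NetworkModel", name = as.character(meta$name),
      inputShape = as.integer(unlist(meta$input_shape)),
      layers = layers, ablation = abl)
}
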