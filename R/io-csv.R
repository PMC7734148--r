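## ---------------------------------------------------------------------------
## CSV file formats: stimulus tables, network masks, response matrices.
##
## Stimulus and mask files are UTF-8 CSV. Stimulus files start with a
## "#key=value" preamble (required keys: type, dir; optional: title),
## followed by exactly one header row and data rows. All channel/unit
## indices in mask files are 0-based.
## ---------------------------------------------------------------------------

bestEffortNumeric <- function(v) {
  suppressWarnings(num <- as.numeric(v))
  if (!anyNA(num) || all(is.na(num) == (is.na(v) | v == ""))) {
    if (any(!is.na(num))) return(num)
  }
  v
}

#' Read a stimulus CSV file
#'
#' Parses the preamble (\code{#type=...}, \code{#dir=...}, optional
#' \code{#title=...}), the header row and the data rows into a
#' \linkS4class{StimulusTable}. Attribute columns are typed by best-effort
#' numeric parse and kept as strings otherwise. Row order is preserved.
#'
#' @param path file path.
#' @return a \linkS4class{StimulusTable}.
#' @export
readStimulusTable <- function(path) {
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  pre <- grep("^#", lines)
  meta <- list()
  for (l in lines[pre]) {
    kv <- sub("^#", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  for (key in c("type", "dir"))
    if (is.null(meta[[key]]))
      formatError(sprintf("stimulus file preamble lacks required key '%s'", key))
  body <- lines[setdiff(seq_along(lines), pre)]
  if (length(body) == 0) formatError("stimulus file has no header row")
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", check.names = FALSE)
  if (!"stim_id" %in% names(df))
    formatError("stimulus file header lacks required column 'stim_id'")
  if (anyDuplicated(df$stim_id))
    validationError(sprintf("duplicate stim_id values: %s",
      paste(unique(df$stim_id[duplicated(df$stim_id)]), collapse = ", ")))
  for (cl in setdiff(names(df), "stim_id")) {
    if (cl %in% c("onset", "duration")) {
      suppressWarnings(df[[cl]] <- as.numeric(df[[cl]]))
    } else {
      df[[cl]] <- bestEffortNumeric(df[[cl]])
    }
  }
  StimulusTable(df, stimDir = meta$dir, stimType = meta$type)
}

#' Write a stimulus CSV file
#'
#' Inverse of \code{\link{readStimulusTable}}: the written file reads back
#' into a structurally equal table (numeric attributes survive exactly).
#'
#' @param table a \linkS4class{StimulusTable}.
#' @param path destination path.
#' @export
writeStimulusTable <- function(table, path) {
  validObject(table)
  df <- table@data
  for (cl in names(df)) if (is.numeric(df[[cl]])) df[[cl]] <- numToChr(df[[cl]])
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) ioError(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  writeLines(c(sprintf("#type=%s", table@stimType),
               sprintf("#dir=%s", table@stimDir)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a network mask CSV file
#'
#' Format: header \code{layer,channels,units}; one row per layer;
#' \code{channels} is a semicolon-separated list of 0-based indices or
#' \code{all}; \code{units} is a semicolon-separated list of \code{row:col}
#' pairs (0-based) or \code{all}.
#'
#' @param path file path.
#' @return a \linkS4class{MaskSpec}.
#' @export
readMaskSpec <- function(path) {
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, colClasses = "character")
  for (key in c("layer", "channels", "units"))
    if (!key %in% names(df))
      formatError(sprintf("mask file lacks required column '%s'", key))
  if (anyDuplicated(df$layer))
    validationError(sprintf("layer listed more than once: %s",
      paste(unique(df$layer[duplicated(df$layer)]), collapse = ", ")))
  entries <- list()
  for (i in seq_len(nrow(df))) {
    chs <- trimws(df$channels[i])
    ch <- if (chs %in% c("all", "")) "all" else {
      v <- suppressWarnings(as.integer(strsplit(chs, ";", fixed = TRUE)[[1]]))
      if (anyNA(v)) formatError(sprintf("bad channel list '%s'", chs))
      if (any(v < 0)) validationError("channel indices must be non-negative")
      v
    }
    uns <- trimws(df$units[i])
    un <- if (uns %in% c("all", "")) "all" else {
      pairs <- strsplit(strsplit(uns, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      if (any(lengths(pairs) != 2))
        formatError(sprintf("bad unit list '%s' (expected r:c pairs)", uns))
      m <- t(vapply(pairs, function(p) suppressWarnings(as.integer(p)),
                    integer(2)))
      if (anyNA(m)) formatError(sprintf("bad unit list '%s'", uns))
      if (any(m < 0)) validationError("unit coordinates must be non-negative")
      m
    }
    entries[[df$layer[i]]] <- list(channels = ch, units = un)
  }
  new("MaskSpec", entries = entries)
}

#' Write a network mask CSV file
#'
#' Inverse of \code{\link{readMaskSpec}}; \code{"all"} selections are
#' written as the literal \code{all}.
#'
#' @param mask a \linkS4class{MaskSpec}.
#' @param path destination path.
#' @export
writeMaskSpec <- function(mask, path) {
  validObject(mask)
  rows <- vapply(names(mask@entries), function(ln) {
    e <- mask@entries[[ln]]
    ch <- if (identical(e$channels, "all")) "all"
          else paste(e$channels, collapse = ";")
    un <- if (identical(e$units, "all")) "all"
          else paste(apply(e$units, 1, paste, collapse = ":"), collapse = ";")
    sprintf("%s,%s,%s", ln, ch, un)
  }, character(1))
  tryCatch(writeLines(c("layer,channels,units", rows), path),
           error = function(e) ioError(sprintf("cannot write '%s'", path)))
  invisible(NULL)
}

#' Load a response matrix
#'
#' Delimited format: header \code{stim_id,<site1>,<site2>,...}, one row per
#' stimulus; cells must be numeric (NaN allowed -- sites containing NaN are
#' kept and flagged by downstream model fitting, not dropped here). The
#' HDF5 format is the layout written by \code{\link{writeResponseMatrix}}.
#'
#' @param path file path.
#' @param format "delimited" or "hdf5".
#' @return a \linkS4class{ResponseMatrix}.
#' @export
loadResponseMatrix <- function(path, format = c("delimited", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) ioError(sprintf("no such file: %s", path))
  if (format == "hdf5") {
    vals <- h5TryRead(path, "values")
    return(ResponseMatrix(vals,
                          stimIds = as.character(h5TryRead(path, "stim_ids")),
                          siteIds = as.character(h5TryRead(path, "site_ids"))))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) formatError("empty response file")
  fields <- strsplit(lines, ",", fixed = TRUE)
  hdr <- fields[[1]]
  if (hdr[1] != "stim_id")
    formatError("response file header must start with 'stim_id'")
  siteIds <- hdr[-1]
  nc <- length(hdr)
  body <- fields[-1]
  ragged <- which(lengths(body) != nc)
  if (length(ragged))
    formatError(sprintf("ragged row(s): %s",
                        paste(ragged + 1L, collapse = ", ")))
  stimIds <- vapply(body, `[[`, character(1), 1)
  vals <- matrix(NA_real_, length(body), nc - 1L)
  for (i in seq_along(body)) {
    raw <- body[[i]][-1]
    suppressWarnings(num <- as.numeric(raw))
    bad <- which(is.na(num) & !toupper(raw) %in% c("NAN", "NA", ""))
    if (length(bad))
      formatError(sprintf("non-numeric cell '%s' at row %d, column %d",
                          raw[bad[1]], i + 1L, bad[1] + 1L))
    vals[i, ] <- num
  }
  ResponseMatrix(vals, stimIds = stimIds, siteIds = siteIds)
}

#' Write a response matrix
#'
#' @param rm a \linkS4class{ResponseMatrix}.
#' @param path destination path.
#' @param format "delimited" or "hdf5".
#' @export
writeResponseMatrix <- function(rm, path, format = c("delimited", "hdf5")) {
  format <- match.arg(format)
  validObject(rm)
  if (format == "hdf5") {
    h5Recreate(path)
    rhdf5::h5write(rm@values, path, "values")
    rhdf5::h5write(rm@stimIds, path, "stim_ids")
    rhdf5::h5write(rm@siteIds, path, "site_ids")
    rhdf5::h5closeAll()
    return(invisible(NULL))
  }
  hdr <- paste(c("stim_id", rm@siteIds), collapse = ",")
  rows <- vapply(seq_along(rm@stimIds), function(i)
    paste(c(rm@stimIds[i], numToChr(rm@values[i, ])), collapse = ","),
    character(1))
  tryCatch(writeLines(c(hdr, rows), path),
           error = function(e) ioError(sprintf("cannot write '%s'", path)))
  invisible(NULL)
}
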