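## Internal helpers: condition classes and seeded evaluation.

#' @keywords internal
dnnCondition <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dnnmapr_error")))
}

formatError     <- function(msg) dnnCondition(msg, "dnnmapr_format_error")
validationError <- function(msg) dnnCondition(msg, "dnnmapr_validation_error")
usageError      <- function(msg) dnnCondition(msg, "dnnmapr_usage_error")
bindingError    <- function(msg) dnnCondition(msg, "dnnmapr_binding_error")
alignmentError  <- function(msg) dnnCondition(msg, "dnnmapr_alignment_error")
ioError         <- function(msg) dnnCondition(msg, "dnnmapr_io_error")

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that no call perturbs the user's global RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

## Column means/sds for train-fold standardization; constant columns get
## sd 1 so they standardize to 0 rather than NaN.
colStats <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

applyStats <- function(x, st) sweep(sweep(x, 2, st$mean, "-"), 2, st$sd, "/")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Number formatting that survives a read/write roundtrip bit-exactly.
numToChr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.nan(v)) return("NaN")
    if (is.na(v)) return("")
    formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}
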