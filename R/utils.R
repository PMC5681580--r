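#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor lm median optimize predict quantile rbinom
#'   rgeom rlnorm rnorm runif sd setNames var aggregate coef model.matrix
#'   complete.cases nls qnorm
#' @importFrom utils read.csv write.csv head tail packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Simple condition-logged message used by all I/O and filtering steps.
br_log <- function(..., verbose = getOption("borealrings.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[borealrings] ", ...)
  invisible(NULL)
}

stop_br <- function(...) stop(..., call. = FALSE)

## Polynomial rolling hash (mod 2^31-1) of a character scalar; used for run
## manifests only, not security.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Derive a stage seed from a global seed; kept < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}
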