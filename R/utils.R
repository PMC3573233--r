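#' @keywords internal
"_PACKAGE"

#' @importFrom stats mad median optim pnorm qnorm rnorm runif sd var
#' @importFrom utils modifyList read.csv write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib bgdcm, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Integrate a sampled function over a frequency band (trapezoidal rule)
#'
#' @param f frequencies (Hz), strictly increasing
#' @param y values at `f`
#' @return scalar integral
#' @keywords internal
trapz <- function(f, y) {
  n <- length(f)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(f)) / 2
}

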