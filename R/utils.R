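#' @useDynLib ligandtree
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx lm median pchisq pt qnorm quantile rbinom rnorm
#'   runif setNames t.test uniroot wilcox.test coef predict
#' @importFrom utils read.csv read.delim write.csv combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

ltStop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("ligandtree_", class), "ligandtree_error",
              "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

#' FNV-1a hash of an R object
#'
#' Stable 32-bit hash of the serialized object, used to stamp artifacts
#' with the configuration that produced them.
#'
#' @param x any serializable R object.
#' @return hexadecimal character scalar.
#' @export
configHash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  # skip the serialization header (platform-dependent R version bytes)
  bytes <- as.integer(bytes[-seq_len(14)])
  # 31-bit polynomial rolling hash, exact in double arithmetic
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default measurement time grid
#'
#' The stimulation time grid used throughout: 0, 2, 4, 6, 8, 10, 15, 30,
#' 60, 90, 120 and 240 minutes.
#'
#' @return numeric vector of times (min).
#' @export
defaultTimeGrid <- function() {
  c(0, 2, 4, 6, 8, 10, 15, 30, 60, 90, 120, 240)
}

trapzAuc <- function(x, y) {
  if (length(x) < 2) return(0)
  pracma::trapz(x, y)
}
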