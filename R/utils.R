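#' @useDynLib modscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree hclust median rnorm runif sd setNames
#' @importFrom utils combn write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population standard deviation (denominator n), used for null-distribution
# moments where the z standardizes against the sampled null itself.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# Derive a per-(i, j) RNG seed from a base seed so results do not depend on
# iteration order. Accepts integers or strings (hashed); kept below 2^31 - 1.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) + 48271 * str_hash(i) + 10007 * str_hash(j)) %%
               2147483629)
}

# Deterministic polynomial hash of a string (identity for numbers), so
# per-entity seeds depend on names, not iteration order.
str_hash <- function(x) {
  if (is.numeric(x)) return(as.double(x))
  h <- 0
  for (code in utf8ToInt(as.character(x))) h <- (h * 131 + code) %% 2147483629
  h
}

msg <- function(...) message("[modscore] ", sprintf(...))
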