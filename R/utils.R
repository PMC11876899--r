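#' @useDynLib rstddm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats binomial coef cor glm lm pbeta quantile rnorm runif sd
#'   setNames var integrate rgamma rbinom plogis median predict
NULL

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Every stochastic stage of the pipeline draws its RNG stream from
#' `(seed, stage-name, unit-id)` so stages and subjects are independent and
#' no global RNG state is shared.  The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param ... stage names, subject ids, indices; coerced to character and
#'   folded into the hash.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.character(as.integer(seed)), vapply(list(...), as.character, ""))
  key <- paste(parts, collapse = "\r")
  # FNV-1a over the key bytes, folded to 31 bits, done in double precision
  # (exact for integers < 2^53)
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h %% 2147483646) + 1L
}

# xor of two non-negative doubles holding < 2^31 integer values
bitwXor_dbl <- function(a, b) {
  as.double(bitwXor(as.integer(a %% 2147483648), as.integer(b)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

STATUS_LEVELS <- c("better", "equal", "worse")

as_status <- function(x) {
  s <- tolower(as.character(x))
  bad <- setdiff(unique(s), STATUS_LEVELS)
  if (length(bad) > 0)
    stopf("unknown status label(s): %s", paste(bad, collapse = ", "))
  factor(s, levels = STATUS_LEVELS)
}
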