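# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a key
#'
#' Child seeds keep independent random streams (per fold, per filter, per
#' tree, ...) reproducible from one master seed without the streams
#' interfering with each other. The hash is a simple polynomial rolling hash
#' over the key string, reduced modulo 2^31 - 1 so the result is always a
#' valid R integer seed.
#'
#' @param seed Integer master seed.
#' @param ... Key components (coerced to character) identifying the stream.
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 17
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h %% 2147483646) + 1L
}

# stop() with a consistent prefix for input validation failures
fail_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

# trapezoidal rule on an (x, y) grid
trapezoid <- function(x, y) {
  k <- length(x)
  sum(diff(x) * (y[-1] + y[-k]) / 2)
}
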