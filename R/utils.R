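# Internal helpers shared across modules.

#' @importFrom stats rnorm runif pt qnorm cor sd binom.test dgamma convolve
#'   setNames
#' @importFrom utils read.csv write.csv
NULL

# Derive a stream-specific RNG seed from a base seed and a tag path, so every
# stochastic operation is a pure function of (seed, tag) and streams do not
# collide. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147480009)
}

# 0-based linear voxel index (x fastest) <-> 1-based R array position.
lin_to_pos <- function(idx) idx + 1L
pos_to_lin <- function(pos) pos - 1L

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

# The three contrast keys, in the fixed block order used everywhere.
CONTRAST_KEYS <- c("M-F", "M-S", "F-S")
CONDITIONS <- c("M", "F", "S")
REGRESSOR_KEYS <- c("BDI", "AAI")
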