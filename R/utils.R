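#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rnorm rpois qpois setNames
#' @importFrom utils write.table read.table
NULL

# Deterministically derive a module-level seed from a master seed and a tag.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# round() uses banker's rounding; sampling counts are defined as round-half-up
# so that e.g. 0.5 * 5 transcripts -> 3, reproducibly across platforms.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

is_fraction <- function(x, lo = 0, hi = 1, open_lo = TRUE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) return(FALSE)
  lo_ok <- if (open_lo) x > lo else x >= lo
  hi_ok <- if (open_hi) x < hi else x <= hi
  lo_ok && hi_ok
}
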