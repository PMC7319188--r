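#' Derive a replicate seed from a base seed
#'
#' Deterministic seed derivation used throughout the package so that every
#' random stage of every replicate draws from its own seed. Seeds are spaced
#' by `stride` per replicate with a small stage offset, and folded into the
#' 32-bit signed range R requires.
#'
#' @param base_seed integer root seed.
#' @param replicate replicate index (1-based; 0 for per-run draws such as the
#'   geography).
#' @param stage integer stage offset in `0:(stride - 1)`.
#' @param stride spacing between consecutive replicates (number of random
#'   stages per replicate).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(base_seed, replicate, stage = 0L, stride = 4L) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L, is.finite(base_seed))
  stopifnot(stage >= 0L, stage < stride)
  m <- 2147483647 # 2^31 - 1
  s <- (as.double(base_seed) %% m) + as.double(stride) * replicate + stage
  as.integer(s %% m)
}

#' @keywords internal
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop(sprintf(
      "`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

#' @keywords internal
match_scale <- function(scale) {
  match.arg(scale, c("natural", "log"))
}
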