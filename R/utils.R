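# Shared constants and small helpers.

#' Frame rate of the facial action unit stream
#'
#' AU activations are sampled at 15 frames per second, so one frame spans
#' 1000/15 = 66.7 ms.
#' @return Frames per second (15).
#' @export
au_fps <- function() 15L

#' Duration of one AU frame in milliseconds
#' @return 1000/15 ms.
#' @export
frame_duration_ms <- function() 1000 / au_fps()

#' Derive a reproducible child seed
#'
#' All generators draw their randomness from one global seed; per-unit
#' (participant, dyad, bootstrap) child seeds are derived deterministically so
#' that any subset of units is reproducible on its own.
#'
#' @param seed Integer parent seed.
#' @param index Integer unit index (1-based).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # affine congruential mix; keeps results within 32-bit integer range
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 11939) %%
               2147483647)
}

#' Truncated normal sampler
#'
#' Inverse-CDF sampler for a normal distribution truncated to `[lo, hi]`.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the parent normal.
#' @param lo,hi Truncation bounds.
#' @return Numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  stopifnot(lo < hi, sd > 0)
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# internal: stop() with call. = FALSE everywhere
abort <- function(...) stop(..., call. = FALSE)

# internal: check a data.frame has the named columns
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
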