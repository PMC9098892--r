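#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop() with the caller's message, no call echo.
abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Derive a child seed from a global seed
#'
#' One global seed is expanded into per-module seeds by fixed affine jumps,
#' so that e.g. the spine simulator and the calcium simulator never consume
#' the same random stream. The scheme is `(seed + 104729 * index) mod (2^31 - 1)`
#' (104729 is the 10,000th prime; the modulus keeps seeds in integer range).
#'
#' @param seed integer global seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
#' @examples
#' child_seed(1, 0)
#' child_seed(1, 3)
child_seed <- function(seed, index) {
  abort_if(!is.numeric(seed) || length(seed) != 1L, "seed must be a single number")
  abort_if(!is_count(index), "index must be a non-negative integer")
  as.integer((as.numeric(seed) + 104729 * index) %% (2^31 - 1))
}

#' Mean and standard error of the mean, excluding undefined values
#'
#' The package carries undefined quantities (e.g. a turnover rate whose
#' previous-session denominator is zero) as `NA`, never as zero. This helper
#' aggregates such vectors the way figure legends report them: mean +/- SEM
#' over the defined values, with the number excluded reported alongside.
#'
#' @param x numeric vector, possibly containing `NA` markers.
#' @return a one-row data.frame with columns `mean`, `sem`, `n`, `n_excluded`.
#'   `sem` is `NA` when fewer than two defined values exist.
#' @export
mean_sem <- function(x) {
  defined <- x[!is.na(x)]
  n <- length(defined)
  data.frame(
    mean = if (n >= 1L) mean(defined) else NA_real_,
    sem = if (n >= 2L) stats::sd(defined) / sqrt(n) else NA_real_,
    n = n,
    n_excluded = sum(is.na(x))
  )
}
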