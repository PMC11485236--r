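#' @keywords internal
#' @import methods
#' @importFrom stats sd rpois runif rnorm rlnorm rgamma plogis pf pbinom
#'   dbinom pnorm cor wilcox.test aov TukeyHSD setNames median
#' @importFrom utils read.delim write.table
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed` and
#' restores the previous state afterwards, so seeded package functions do
#' not disturb the caller's RNG stream.
#'
#' @param seed Integer scalar seed. Must be supplied (deterministic
#'   behaviour is mandatory for all stochastic operations).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required; stochastic results must be reproducible")
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## spikes in [onset + start, onset + end) for each onset; half-open so a
## spike exactly on the end boundary is never double-counted.
## findInterval(x, sp, left.open = TRUE) = #{sp < x} for sorted sp.
countSpikesInWindows <- function(spikes, onsets, window) {
  if (is.unsorted(spikes)) spikes <- sort(spikes)
  findInterval(onsets + window[2L], spikes, left.open = TRUE) -
    findInterval(onsets + window[1L], spikes, left.open = TRUE)
}

windowLength <- function(window) window[2L] - window[1L]

checkWindow <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2L || anyNA(window))
    stop("'", what, "' must be numeric of length 2")
  if (window[2L] <= window[1L])
    stop("'", what, "' must satisfy end > start")
  invisible(window)
}

#' @importFrom utils packageName
logMsg <- function(...) {
  message("[piriform] ", ...)
}
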