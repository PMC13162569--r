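# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded sampling
#' inside the package never disturbs user-level reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# sample() without the length-1 surprise
sample_exact <- function(x, size) {
  if (length(x) == 0L || size == 0L) return(x[integer(0)])
  x[sample.int(length(x), size)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pkg <- function(...) stop(sprintf(...), call. = FALSE)
warn_pkg <- function(...) warning(sprintf(...), call. = FALSE)
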