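#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state on exit, so seeded generators never perturb the caller's stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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

# derive a reproducible child seed (kept below 2^31) from a parent seed
childSeed <- function(seed, offset) {
  (as.double(seed) * 7919 + offset * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared warning collector: functions append run-time warnings here so the
# pipeline log can report dropped features, fallback k, excluded pairs etc.
noteWarning <- function(msg, call. = FALSE) {
  warning(msg, call. = call.)
  invisible(msg)
}
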