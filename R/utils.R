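#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state,
#' so seeded package internals never disturb user-level randomness. With
#' `seed = NULL` the expression simply runs under the current state.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## zero-padded id factory: idMaker("F")(3, 12) -> "F003"
.idMaker <- function(prefix) {
  function(i, n) sprintf("%s%0*d", prefix, nchar(as.character(n)), i)
}
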