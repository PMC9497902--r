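## Internal helpers.

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG state is restored afterwards. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Near-equality for wavelength arithmetic.
nearlyInteger <- function(x, tol = 1e-8) abs(x - round(x)) < tol

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
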