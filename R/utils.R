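# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

isWholeNumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) <= tol)
}

# canonical unordered-pair key, used to compare edge sets
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
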