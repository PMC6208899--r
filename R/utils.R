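# Internal helpers shared across modules.

# Run code with a local RNG seed, restoring the caller's random state so that
# no simulator leaks global RNG side effects.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

assertProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  as.numeric(x)
}

assertProbVector <- function(p, name, tol = 1e-8) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop(sprintf("`%s` must be non-negative and finite", name), call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("`%s` must sum to 1 (got %.6f)", name, sum(p)),
         call. = FALSE)
  p
}

# Expression matrices are plain numeric matrices, genes in rows, samples in
# columns, with unique dimnames on both axes.
assertExpressionMatrix <- function(x, name = "matrix", allowNA = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", name),
         call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("`%s` must have gene row names and sample column names",
                 name), call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate gene identifiers in `%s`: %s", name,
                 paste(unique(rownames(x)[duplicated(rownames(x))]),
                       collapse = ", ")), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(sprintf("duplicate sample identifiers in `%s`: %s", name,
                 paste(unique(colnames(x)[duplicated(colnames(x))]),
                       collapse = ", ")), call. = FALSE)
  if (!allowNA && any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}
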