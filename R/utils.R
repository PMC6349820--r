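# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so generators behave as pure functions of their
# arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# coerce an expression input (matrix or data.frame with cell-id column
# already as rownames) to a numeric matrix with feature column names
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expression data must be a numeric matrix (cells x features)")
  if (is.null(colnames(x)))
    stopf("expression matrix must carry feature names as column names")
  if (anyDuplicated(colnames(x)))
    stopf("duplicate feature names: %s",
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  x
}
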