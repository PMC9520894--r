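# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so package functions never disturb the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Validate a gene x sample expression matrix: finite, non-negative, uniquely
# named on both margins. Returns the matrix invisibly so callers can pipe.
validate_expression_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples).", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("duplicate gene identifiers in `%s`: %s", arg,
                  paste(unique(rownames(x)[duplicated(rownames(x))]),
                        collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("duplicate sample identifiers in `%s`: %s", arg,
                  paste(unique(colnames(x)[duplicated(colnames(x))]),
                        collapse = ", ")))
  }
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(sprintf(
      "expression values must be finite and >= 0; offending entry gene '%s', sample '%s' (value %s)",
      rownames(x)[i], colnames(x)[j], format(x[i, j])))
  }
  invisible(x)
}

# match gene ids exactly (case-sensitive), optionally through an alias map
# (named character vector: names = foreign symbol, values = matrix symbol)
resolve_gene_ids <- function(ids, universe, alias_map = NULL) {
  if (!is.null(alias_map)) {
    hit <- ids %in% names(alias_map)
    ids[hit] <- unname(alias_map[ids[hit]])
  }
  ids
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
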