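## Internal helpers shared across modules.

# Run `expr` under a temporarily-set RNG seed (NULL = use current stream),
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("'seed' must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Prefix-stable stream of sub-seeds: the first k values are identical for
# any n >= k, so growing a simulation never perturbs earlier units.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Atomic text write: write to a temp file in the same directory, then
# rename, so readers never observe a partially written file.
atomic_write <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not rename ", tmp, " -> ", path)
  ok <- TRUE
  invisible(path)
}

# Tie-stable descending order: larger score first, equal scores resolved by
# ascending index so selections are reproducible.
order_desc_stable <- function(score) order(-score, seq_along(score))

.assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop("'", name, "' must be a single positive number")
  }
  invisible(x)
}
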