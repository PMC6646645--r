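# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Fan a master seed out into n reproducible sub-seeds (kept < 2^31).
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Accept a BinaryMask or a plain {0,1} matrix; return the matrix.
as_mask_matrix <- function(x, arg = "mask") {
  if (is(x, "BinaryMask")) return(x@grid)
  if (is.matrix(x)) {
    if (!all(x %in% c(0, 1)))
      stop(arg, " must contain only 0 and 1", call. = FALSE)
    return(x)
  }
  stop(arg, " must be a BinaryMask or a {0,1} matrix", call. = FALSE)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
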