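# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically mix a master seed with stage/subject/density offsets into
# a 32-bit-safe positive integer. Collisions are harmless (different streams),
# what matters is reproducibility of the mapping.
derive_seed <- function(master, ...) {
  offs <- c(...)
  x <- as.double(master) %% 2147483647
  primes <- c(7919, 104729, 1299709, 15485863, 32452843)
  for (i in seq_along(offs)) {
    p <- primes[((i - 1L) %% length(primes)) + 1L]
    x <- (x * 48271 + as.double(offs[i]) * p + i) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

# Round half away from zero (base round() is banker's).
round_half_up <- function(x) floor(x + 0.5)

# Validate a binary adjacency matrix: square, symmetric, 0/1, zero diagonal.
check_adjacency <- function(A, arg = "A") {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (any(!A %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (entries 0 or 1).", arg))
  }
  if (any(diag(A) != 0)) {
    abort(sprintf("`%s` must have a zero diagonal (no self-loops).", arg))
  }
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    abort(sprintf("`%s` must be symmetric (undirected graph).", arg))
  }
  invisible(A)
}

as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
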