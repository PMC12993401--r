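# Small-graph constructors and enumeration used across tests.

adj_empty <- function(n) matrix(0, n, n)

adj_complete <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  A
}

adj_ring <- function(n) {
  A <- adj_empty(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    A[i, j] <- A[j, i] <- 1
  }
  A
}

adj_star <- function(n_leaves) {
  A <- adj_empty(n_leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1
  A
}

adj_path <- function(n) {
  A <- adj_empty(n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

adj_from_edges <- function(n, edges) {
  A <- adj_empty(n)
  for (e in edges) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  }
  A
}

# Two disjoint cliques of size k (nodes 1..k and k+1..2k).
adj_two_cliques <- function(k, bridge = FALSE) {
  A <- adj_empty(2 * k)
  A[1:k, 1:k] <- 1
  A[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(A) <- 0
  if (bridge) A[k, k + 1] <- A[k + 1, k] <- 1
  A
}

rand_adj <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(runif(sum(up)) < p)
  A + t(A)
}

# Watts-Strogatz ring lattice with rewiring (canonical small-world graph).
adj_watts_strogatz <- function(n, k, p, seed) {
  set.seed(seed)
  g <- igraph::sample_smallworld(1, n, k / 2, p)
  g <- igraph::simplify(g)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

mask_to_adj <- function(mask, n, pairs) {
  A <- matrix(0, n, n)
  on <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) != 0L)
  if (length(on)) {
    A[pairs[on, , drop = FALSE]] <- 1
    A[pairs[on, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

adj_is_connected <- function(A) {
  n <- nrow(A)
  seen <- 1L
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(rowSums(A[, frontier, drop = FALSE]) > 0)
    new <- setdiff(nb, seen)
    seen <- c(seen, new)
    frontier <- new
  }
  length(seen) == n
}

# All connected graphs on exactly n labelled nodes, reduced to one
# representative per isomorphism class (canonical labelling via igraph).
connected_graphs_upto_iso <- function(n) {
  if (n == 1) return(list(adj_empty(1)))
  pairs <- t(utils::combn(n, 2))
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1L)) {
    A <- mask_to_adj(mask, n, pairs)
    if (!adj_is_connected(A)) next
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    cp <- igraph::canonical_permutation(g)
    gg <- igraph::permute(g, cp$labeling)
    key <- paste(
      as.vector(igraph::as_adjacency_matrix(gg, sparse = FALSE)),
      collapse = ""
    )
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- A
    }
  }
  out
}
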