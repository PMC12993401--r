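#' Null-model ensemble configuration
#'
#' @param n_nulls Number of rewired reference networks per graph (default
#'   100; the test-scale simulations use far fewer).
#' @param swaps_per_edge Attempted degree-preserving double-edge swaps per
#'   edge (default 10).
#' @return A named list of class `null_config`.
#' @export
null_config <- function(n_nulls = 100, swaps_per_edge = 10) {
  if (n_nulls < 1 || swaps_per_edge < 1) {
    abort("n_nulls and swaps_per_edge must be >= 1.")
  }
  structure(
    list(n_nulls = as.integer(n_nulls),
         swaps_per_edge = as.integer(swaps_per_edge)),
    class = "null_config"
  )
}

#' Degree-preserving rewiring (double-edge swap)
#'
#' Maslov–Sneppen rewiring: repeatedly swaps the endpoints of two random
#' edges, rejecting swaps that would create self-loops or multi-edges, so the
#' result is a simple graph with exactly the original degree sequence.
#' Graphs with fewer than 2 edges (or with no legal swap, e.g. complete
#' graphs) come back unchanged.
#'
#' @param A Binary adjacency matrix.
#' @param swaps_per_edge Attempted swaps per edge.
#' @param seed Integer seed; the rewiring is deterministic given it.
#' @return A rewired binary adjacency matrix with identical degree sequence.
#' @export
rewire_preserving_degree <- function(A, swaps_per_edge = 10, seed = 1L) {
  check_adjacency(A)
  g <- as_igraph(A)
  m <- igraph::ecount(g)
  if (m < 2) {
    warn("Fewer than 2 edges: returning the graph unchanged.")
    return(A)
  }
  rg <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = swaps_per_edge * m)
  ))
  B <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
  dimnames(B) <- dimnames(A)
  B
}

#' Small-world normalization against rewired nulls
#'
#' Computes the normalized clustering coefficient gamma = Cp / <Cp_null>, the
#' normalized characteristic path length lambda = Lp / <Lp_null>, and
#' small-worldness sigma = gamma / lambda, where the null means are taken
#' over an ensemble of degree-preserving rewired versions of the graph. Null
#' path lengths use the same finite-pairs convention as the real graph.
#'
#' @param A Binary adjacency matrix.
#' @param n_nulls,swaps_per_edge Ensemble size and rewiring effort.
#' @param seed Master seed for the ensemble (null k uses a derived stream).
#' @param null_graphs Optional list of pre-built null adjacency matrices,
#'   overriding ensemble generation (ensemble of the graph itself gives
#'   gamma = lambda = sigma = 1).
#' @param cp,lp Optional precomputed Cp / Lp of `A` (skips recomputation).
#' @return A one-row tibble: `gamma`, `lambda`, `sigma`, `cp`, `lp`,
#'   `null_cp_mean`, `null_lp_mean`, `n_nulls`.
#' @export
small_world_normalize <- function(A, n_nulls = 100, swaps_per_edge = 10,
                                  seed = 1L, null_graphs = NULL,
                                  cp = NULL, lp = NULL) {
  check_adjacency(A)
  if (is.null(cp)) cp <- mean_clustering(A)
  if (is.null(lp)) lp <- as.numeric(char_path_length(A))
  if (!is.null(null_graphs)) {
    null_cp <- vapply(null_graphs, mean_clustering, numeric(1))
    null_lp <- vapply(
      null_graphs,
      function(B) suppressWarnings(as.numeric(char_path_length(B))),
      numeric(1)
    )
    return(sw_assemble(cp, lp, null_cp, null_lp))
  }
  sw_normalize_g(as_igraph(A), cp = cp, lp = lp, n_nulls = n_nulls,
                 swaps_per_edge = swaps_per_edge, seed = seed)
}

# igraph-native ensemble loop (hot path of metric_curves).
sw_normalize_g <- function(g, cp, lp, n_nulls, swaps_per_edge, seed) {
  m <- igraph::ecount(g)
  null_cp <- numeric(n_nulls)
  null_lp <- numeric(n_nulls)
  for (k in seq_len(n_nulls)) {
    rg <- if (m < 2) g else with_seed(derive_seed(seed, k), igraph::rewire(
      g, igraph::keeping_degseq(loops = FALSE, niter = swaps_per_edge * m)
    ))
    null_cp[k] <- mean(igraph::transitivity(rg, type = "localundirected",
                                            isolates = "zero"))
    null_lp[k] <- igraph::mean_distance(rg, directed = FALSE,
                                        unconnected = TRUE)
  }
  sw_assemble(cp, lp, null_cp, null_lp)
}

sw_assemble <- function(cp, lp, null_cp, null_lp) {
  ncp <- mean(null_cp)
  nlp <- mean(null_lp)
  gamma <- if (isTRUE(ncp > 0)) cp / ncp else {
    warn("Null ensemble has zero mean clustering; gamma undefined.")
    NA_real_
  }
  lambda <- lp / nlp
  tibble::tibble(
    gamma = gamma, lambda = lambda, sigma = gamma / lambda,
    cp = cp, lp = lp, null_cp_mean = ncp, null_lp_mean = nlp,
    n_nulls = length(null_cp)
  )
}
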