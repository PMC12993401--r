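# Binary graph metrics. All functions take an N x N binary symmetric
# adjacency matrix with zero diagonal; graphs are simple and undirected,
# mirroring the binarized-network analysis.

#' Per-node clustering coefficient
#'
#' Watts–Strogatz binary clustering: for a node of degree k >= 2 the fraction
#' of its neighbour pairs that are connected, 2 t / (k (k - 1)); 0 for degree
#' below 2.
#'
#' @param A Binary adjacency matrix.
#' @return Numeric vector of per-node values in \[0, 1\].
#' @export
clustering_coef <- function(A) {
  check_adjacency(A)
  g <- as_igraph(A)
  igraph::transitivity(g, type = "localundirected", isolates = "zero")
}

#' Mean clustering coefficient (Cp)
#' @inheritParams clustering_coef
#' @return Mean of [clustering_coef()] over all nodes.
#' @export
mean_clustering <- function(A) mean(clustering_coef(A))

#' Characteristic path length (Lp)
#'
#' Mean shortest-path distance over reachable ordered node pairs. Unreachable
#' pairs are excluded from the mean and their count is attached as attribute
#' `"unreachable_pairs"` (non-zero means the graph is disconnected).
#'
#' @param A Binary adjacency matrix with at least 2 nodes.
#' @return Scalar Lp (NA, with a warning, if no pair is reachable).
#' @export
char_path_length <- function(A) {
  check_adjacency(A)
  if (nrow(A) < 2) abort("Need at least 2 nodes.")
  D <- igraph::distances(as_igraph(A))
  d <- D[row(D) != col(D)]
  fin <- is.finite(d)
  lp <- if (any(fin)) mean(d[fin]) else {
    warn("No finite node pair: characteristic path length undefined.")
    NA_real_
  }
  structure(lp, unreachable_pairs = sum(!fin))
}

#' Global efficiency (Eg)
#'
#' Mean inverse shortest-path distance over ordered node pairs; unreachable
#' pairs contribute 0, so disconnection is handled natively.
#'
#' @inheritParams clustering_coef
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  if (n < 2) return(0)
  D <- igraph::distances(as_igraph(A))
  mean(1 / D[row(D) != col(D)])
}

#' Per-node nodal efficiency
#'
#' Node i's mean of 1/d(i, j) over j != i, unreachable pairs contributing 0.
#'
#' @inheritParams clustering_coef
#' @return Numeric vector of per-node values in \[0, 1\].
#' @export
nodal_efficiency <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  if (n < 2) return(rep(0, n))
  D <- igraph::distances(as_igraph(A))
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Local efficiency (Eloc)
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours (0 for nodes with fewer than 2 neighbours). Computed by
#' breadth-first search inside each neighbourhood subgraph (compiled).
#'
#' @inheritParams clustering_coef
#' @return Scalar in \[0, 1\].
#' @export
local_efficiency <- function(A) {
  check_adjacency(A)
  local_efficiency_impl(A)
}

local_efficiency_impl <- function(A) {
  storage.mode(A) <- "integer"
  cpp_local_efficiency(A)
}

#' Normalized betweenness centrality
#'
#' Fraction-of-shortest-paths betweenness (Brandes accumulation), divided by
#' its maximum (N-1)(N-2)/2 so values lie in \[0, 1\]. All zeros for N < 3.
#'
#' @inheritParams clustering_coef
#' @return Numeric vector of per-node normalized values.
#' @export
betweenness_centrality <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  raw <- igraph::betweenness(as_igraph(A), directed = FALSE)
  as.numeric(raw) / ((n - 1) * (n - 2) / 2)
}

#' Node degrees
#' @inheritParams clustering_coef
#' @return Integer vector of degrees.
#' @export
node_degree <- function(A) {
  check_adjacency(A)
  as.integer(colSums(A))
}

#' Area under a metric-versus-density curve
#'
#' Trapezoidal integral of a metric over the sparsity grid — the
#' threshold-robust summary used for all statistical comparisons. NaN/NA
#' values propagate with a warning.
#'
#' @param values Metric values, one per density.
#' @param densities The density grid (same length, >= 2, increasing).
#' @return Scalar AUC.
#' @export
auc_sparsity <- function(values, densities) {
  if (length(values) != length(densities) || length(values) < 2) {
    abort("`values` and `densities` must have equal length >= 2.")
  }
  if (anyNA(values) || any(is.nan(values))) {
    warn("NaN/NA in metric curve; AUC is NaN.")
    return(NaN)
  }
  pracma::trapz(as.numeric(densities), as.numeric(values))
}

metric_directions <- function() {
  c(cp = "one_sided_greater", lp = "one_sided_less",
    gamma = "one_sided_greater", lambda = "one_sided_less",
    sigma = "one_sided_greater", eg = "one_sided_greater",
    eloc = "one_sided_greater", q = "one_sided_less")
}

#' Metric curves across the sparsity grid for one connectivity matrix
#'
#' Binarizes `fc` at every grid density and computes the global metrics (Cp,
#' Lp, Eg, Eloc, modularity Q of the slice's greedy partition, and — when a
#' null-model configuration is given — gamma, lambda and sigma against
#' degree-preserving rewired ensembles) plus the nodal metrics (degree, nodal
#' efficiency, normalized betweenness).
#'
#' @param fc Fisher-z connectivity matrix from [fc_matrix()].
#' @param grid A [sparsity_grid()].
#' @param nulls A [null_config()], or `NULL` to skip gamma/lambda/sigma.
#' @param seed Seed for the null ensembles (one stream per density slice).
#' @param global,nodal,include_q Toggles for the metric families.
#' @return A `metric_curves` object: list with tibbles `global` (`density`,
#'   `achieved`, `metric`, `value`) and `nodal` (`density`, `node`, `metric`,
#'   `value`), plus `grid` and `n_nodes`.
#' @export
metric_curves <- function(fc, grid = sparsity_grid(),
                          nulls = null_config(), seed = 1L,
                          global = TRUE, nodal = TRUE, include_q = TRUE) {
  stack <- binarize_stack(fc, grid)
  n <- stack$n
  dens <- stack$densities
  g_rows <- vector("list", length(dens))
  n_rows <- vector("list", length(dens))
  for (k in seq_along(dens)) {
    A <- stack_slice(stack, index = k)
    g <- as_igraph(A)
    vals <- c()
    if (global) {
      D <- igraph::distances(g)
      off <- row(D) != col(D)
      dvec <- D[off]
      fin <- is.finite(dvec)
      lp <- if (any(fin)) mean(dvec[fin]) else NA_real_
      cp <- mean(igraph::transitivity(g, type = "localundirected",
                                      isolates = "zero"))
      vals <- c(cp = cp, lp = lp,
                eg = mean(ifelse(fin, 1 / dvec, 0)),
                eloc = local_efficiency_impl(A))
      if (include_q) {
        part <- detect_communities(A)
        vals <- c(vals, q = part$q)
      }
      if (!is.null(nulls)) {
        sw <- sw_normalize_g(
          g, cp = cp, lp = lp, n_nulls = nulls$n_nulls,
          swaps_per_edge = nulls$swaps_per_edge,
          seed = derive_seed(seed, 101L, k)
        )
        vals <- c(vals, gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
      }
      g_rows[[k]] <- tibble::new_tibble(list(
        density = rep(dens[k], length(vals)),
        achieved = rep(stack$achieved[k], length(vals)),
        metric = names(vals), value = as.numeric(unname(vals))
      ), nrow = length(vals))
    }
    if (nodal) {
      deg <- as.integer(igraph::degree(g))
      ne <- {
        inv <- 1 / igraph::distances(g); diag(inv) <- 0
        rowSums(inv) / (n - 1)
      }
      bc <- if (n < 3) rep(0, n) else {
        as.numeric(igraph::betweenness(g, directed = FALSE)) /
          ((n - 1) * (n - 2) / 2)
      }
      n_rows[[k]] <- tibble::new_tibble(list(
        density = rep(dens[k], 3L * n),
        node = rep(seq_len(n), 3L),
        metric = rep(c("degree", "nodal_efficiency", "betweenness"), each = n),
        value = c(as.numeric(deg), as.numeric(ne), bc)
      ), nrow = 3L * n)
    }
  }
  structure(
    list(
      global = dplyr::bind_rows(g_rows),
      nodal = dplyr::bind_rows(n_rows),
      grid = dens,
      n_nodes = n
    ),
    class = "metric_curves"
  )
}

#' AUC summaries of metric curves
#'
#' @param curves A `metric_curves` object.
#' @return List of tibbles: `global` (`metric`, `auc`) and `nodal` (`node`,
#'   `metric`, `auc`), each integrated over the density grid.
#' @export
curve_auc <- function(curves) {
  stopifnot(inherits(curves, "metric_curves"))
  glob <- NULL
  nod <- NULL
  if (nrow(curves$global)) {
    glob <- curves$global |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(
        auc = auc_sparsity(.data$value, .data$density), .groups = "drop"
      )
  }
  if (nrow(curves$nodal)) {
    nod <- curves$nodal |>
      dplyr::group_by(.data$node, .data$metric) |>
      dplyr::summarise(
        auc = auc_sparsity(.data$value, .data$density), .groups = "drop"
      )
  }
  list(global = glob, nodal = nod)
}
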