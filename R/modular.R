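#' Group-level binary graph at the modular density
#'
#' Averages the baseline Fisher-z connectivity matrices element-wise and
#' binarizes the group mean at a single density (0.15 by default — the
#' sparsest density with minimal probability of spurious connections).
#'
#' @param fc_list A list of N x N Fisher-z matrices (all baseline sessions),
#'   or a tibble with an `fc` list column (filtered to baseline by the
#'   caller).
#' @param density The modular analysis density.
#' @return A binary adjacency matrix.
#' @export
group_graph <- function(fc_list, density = 0.15) {
  if (is.data.frame(fc_list)) fc_list <- fc_list$fc
  if (!length(fc_list)) abort("Need at least one connectivity matrix.")
  dims <- vapply(fc_list, nrow, integer(1))
  if (length(unique(dims)) != 1) abort("All matrices must have the same size.")
  avg <- Reduce(`+`, fc_list) / length(fc_list)
  binarize_at(avg, density)
}

#' Greedy community detection
#'
#' Finds the optimal partition by greedy agglomerative modularity
#' maximization (fast-greedy merging of the community pair with the largest
#' modularity gain until no gain remains), the standard binary-network
#' community detector for group connectomes. The optimizer is deterministic:
#' the same graph always yields the same partition. Partitions with
#' Q >= 0.3 are flagged as non-random community structure.
#'
#' @param A Binary adjacency matrix.
#' @return A `modular_partition`: list with `membership` (node -> module id,
#'   modules numbered by first appearance), `sizes`, `q` (modularity of the
#'   assignment on this graph), `n_modules` and `nonrandom`.
#' @export
detect_communities <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  if (sum(A) == 0) {
    membership <- seq_len(n)
  } else {
    cl <- igraph::cluster_fast_greedy(as_igraph(A))
    membership <- as.integer(igraph::membership(cl))
  }
  # relabel by first appearance for a canonical labelling
  membership <- match(membership, unique(membership))
  q <- modularity_q(A, membership)
  structure(
    list(
      membership = membership,
      sizes = as.integer(table(membership)),
      q = q,
      n_modules = max(membership),
      nonrandom = q >= 0.3,
      n = n
    ),
    class = "modular_partition"
  )
}

#' @export
print.modular_partition <- function(x, ...) {
  cat(sprintf(
    "<modular_partition> %d nodes, %d modules, Q = %.3f%s\n  sizes: %s\n",
    x$n, x$n_modules, x$q,
    if (x$nonrandom) " (non-random, Q >= 0.3)" else "",
    paste(x$sizes, collapse = ", ")
  ))
  invisible(x)
}

#' @rdname detect_communities
#' @param x A `modular_partition`.
#' @param ... Unused.
#' @export
tidy.modular_partition <- function(x, ...) {
  tibble::tibble(node = seq_len(x$n), module = x$membership)
}

#' @rdname detect_communities
#' @export
glance.modular_partition <- function(x, ...) {
  tibble::tibble(
    q = x$q, n_modules = x$n_modules, n_nodes = x$n, nonrandom = x$nonrandom
  )
}

#' Newman modularity of a partition
#'
#' Q = sum over modules of (e_ii - a_i^2): e_ii the fraction of edges inside
#' module i, a_i the fraction of edge endpoints in module i. Zero for an
#' edgeless graph.
#'
#' @param A Binary adjacency matrix.
#' @param membership Integer module assignment covering every node.
#' @return Scalar Q in \[-0.5, 1\].
#' @export
modularity_q <- function(A, membership) {
  check_adjacency(A)
  if (length(membership) != nrow(A)) {
    abort("`membership` must assign every node to a module.")
  }
  m <- sum(A) / 2
  if (m == 0) return(0)
  mods <- sort(unique(membership))
  deg <- colSums(A)
  q <- 0
  for (g in mods) {
    in_g <- membership == g
    e_ii <- sum(A[in_g, in_g]) / 2 / m
    a_i <- sum(deg[in_g]) / (2 * m)
    q <- q + e_ii - a_i^2
  }
  q
}

#' Module-block edge counts
#'
#' Counts, for one subject's binary graph at the modular density, the edges
#' inside each module (diagonal) and between each module pair
#' (off-diagonal), against a fixed group partition.
#'
#' @param A Binary adjacency matrix.
#' @param membership Module assignment (typically the group partition's).
#' @return A K x K symmetric integer matrix; diagonal = intra-module edge
#'   counts, off-diagonal = inter-module. Total (diagonal + upper triangle)
#'   equals the graph's edge count.
#' @export
module_edge_counts <- function(A, membership) {
  check_adjacency(A)
  if (length(membership) != nrow(A)) {
    abort("Partition and graph sizes do not match.")
  }
  k <- max(membership)
  counts <- matrix(0L, k, k)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    ma <- membership[idx[, 1]]
    mb <- membership[idx[, 2]]
    lo <- pmin(ma, mb)
    hi <- pmax(ma, mb)
    for (e in seq_along(lo)) {
      counts[lo[e], hi[e]] <- counts[lo[e], hi[e]] + 1L
    }
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  }
  counts
}

#' Participation coefficient
#'
#' P_i = 1 - sum over modules m of (k_im / k_i)^2, where k_im is node i's
#' edges into module m: 0 when all edges stay in one module, approaching
#' 1 - 1/K for perfectly even spread. Isolated nodes get 0.
#'
#' @inheritParams module_edge_counts
#' @return Numeric vector of per-node values in \[0, 1\].
#' @export
participation_coef <- function(A, membership) {
  check_adjacency(A)
  if (length(membership) != nrow(A)) {
    abort("Partition and graph sizes do not match.")
  }
  deg <- colSums(A)
  k <- max(membership)
  kim <- vapply(seq_len(k), function(m) {
    cols <- membership == m
    if (!any(cols)) return(rep(0, nrow(A)))
    rowSums(A[, cols, drop = FALSE])
  }, numeric(nrow(A)))
  p <- 1 - rowSums((kim / pmax(deg, 1))^2)
  p[deg == 0] <- 0
  p
}

#' Module edge counts for every subject-session
#'
#' @param fc_tbl Tibble `subject`, `session`, `fc` from [cohort_fc()].
#' @param partition A `modular_partition` (the fixed group partition).
#' @param density The modular analysis density.
#' @return A tidy tibble: `subject`, `session`, `module_a`, `module_b`
#'   (`module_a <= module_b`), `type` (`"intra"`/`"inter"`), `count`.
#' @export
cohort_module_counts <- function(fc_tbl, partition, density = 0.15) {
  k <- partition$n_modules
  pairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  rows <- purrr::pmap(
    list(fc_tbl$subject, fc_tbl$session, fc_tbl$fc),
    function(subject, session, fc) {
      A <- binarize_at(fc, density)
      cm <- module_edge_counts(A, partition$membership)
      tibble::tibble(
        subject = subject, session = session,
        module_a = pairs[, 1], module_b = pairs[, 2],
        type = ifelse(pairs[, 1] == pairs[, 2], "intra", "inter"),
        count = cm[pairs]
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Participation coefficients for every subject-session
#'
#' Computed at the modular density only (the partition is defined there).
#'
#' @inheritParams cohort_module_counts
#' @return A tidy tibble `subject`, `session`, `node`, `metric`
#'   (`"participation"`), `value`.
#' @export
cohort_participation <- function(fc_tbl, partition, density = 0.15) {
  rows <- purrr::pmap(
    list(fc_tbl$subject, fc_tbl$session, fc_tbl$fc),
    function(subject, session, fc) {
      A <- binarize_at(fc, density)
      p <- participation_coef(A, partition$membership)
      tibble::tibble(
        subject = subject, session = session,
        node = seq_along(p), metric = "participation", value = p
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Restrict nodal values to implicated modules
#'
#' Selects the nodal rows (AUC metrics plus participation) belonging to the
#' union of implicated modules — the modules that appear in a module pair
#' flagged as a trend by the paired count tests — ready for the restricted
#' statistical family with FDR scoped to that node set per metric.
#'
#' @param nodal_values Tidy tibble `subject`, `session`, `node`, `metric`,
#'   `value` (nodal AUCs and participation stacked).
#' @param partition The group `modular_partition`.
#' @param implicated Integer vector of implicated module ids (possibly
#'   empty).
#' @return The filtered tibble with a `module` column; zero rows (with a
#'   message) when no module is implicated.
#' @export
restricted_nodal_values <- function(nodal_values, partition, implicated) {
  nodes <- which(partition$membership %in% implicated)
  if (!length(implicated) || !length(nodes)) {
    inform("No implicated modules: restricted nodal table is empty.")
    return(dplyr::mutate(nodal_values[0, ], module = integer(0)))
  }
  nodal_values |>
    dplyr::filter(.data$node %in% nodes) |>
    dplyr::mutate(module = partition$membership[.data$node])
}
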