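#' Fisher-z functional connectivity matrix
#'
#' Pearson-correlates every pair of ROI time series, applies Fisher's r-to-z
#' transform, and zeroes negative values (the standard treatment given the
#' contested interpretation of negative resting-state correlations). The
#' diagonal is forced to zero. Off-diagonal correlations of magnitude 1 are
#' clipped to `1 - 1e-7` before the transform to keep z finite, with a
#' warning; this never occurs on real data.
#'
#' @param ts A T x N numeric matrix (rows = time points, columns = ROIs);
#'   T >= 3, no constant column.
#' @return An N x N symmetric nonnegative matrix of Fisher-z values with zero
#'   diagonal, ROI names preserved.
#' @examples
#' ts <- matrix(rnorm(200), 50, 4)
#' fc <- fc_matrix(ts)
#' @export
fc_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) abort("Need at least 3 time points.")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    labs <- colnames(ts) %||% as.character(seq_len(ncol(ts)))
    abort(sprintf(
      "Constant time series for ROI(s): %s",
      paste(labs[sds == 0], collapse = ", ")
    ))
  }
  r <- cor(ts)
  off <- row(r) != col(r)
  if (any(abs(r[off]) >= 1)) {
    warn("Off-diagonal |r| = 1 encountered; clipping to 1 - 1e-7 before Fisher transform.")
    r[off] <- pmin(pmax(r[off], -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- atanh(r)
  z[z < 0] <- 0
  diag(z) <- 0
  z <- (z + t(z)) / 2
  z
}

#' Functional connectivity for every subject-session of a cohort
#'
#' @param cohort A cohort tibble (columns `subject`, `session`, `ts`), e.g.
#'   from [simulate_cohort()] or [read_cohort()].
#' @return The cohort tibble with the `ts` column replaced by an `fc` list
#'   column of Fisher-z matrices.
#' @export
cohort_fc <- function(cohort) {
  out <- dplyr::mutate(cohort, fc = purrr::map(.data$ts, fc_matrix))
  out$ts <- NULL
  out
}

#' Sparsity (density) grid
#'
#' The default grid is 0.05 to 0.50 in steps of 0.01 — 46 density values.
#'
#' @param start,stop,step Grid bounds and increment, all in (0, 1].
#' @return A numeric vector of densities with class `sparsity_grid`.
#' @export
sparsity_grid <- function(start = 0.05, stop = 0.50, step = 0.01) {
  if (!(start > 0 && start < stop && stop <= 1 && step > 0)) {
    abort("Require 0 < start < stop <= 1 and step > 0.")
  }
  n <- round_half_up((stop - start) / step)
  vals <- start + step * (0:n)
  vals <- vals[vals <= stop + 1e-12]
  structure(round(vals, 12), class = c("sparsity_grid", "numeric"))
}

# Number of edges retained at density s in an N-node graph (half-up rounding).
edge_count_at <- function(density, n) {
  as.integer(round_half_up(density * n * (n - 1) / 2))
}

#' Binarize a connectivity matrix across a sparsity grid
#'
#' For each density s the `round(s * N(N-1)/2)` strongest upper-triangle
#' entries are retained as edges, so edge sets are nested along the grid.
#' Ties at the cut are broken deterministically (value descending, then row,
#' then column index ascending). If fewer strictly positive entries exist
#' than a density requests, all positive entries are kept and the achieved
#' density is recorded.
#'
#' @param fc An N x N symmetric nonnegative matrix from [fc_matrix()].
#' @param grid A [sparsity_grid()] (or numeric vector of densities).
#' @return An `adjacency_stack`: a list with `n` (nodes), `densities`
#'   (requested), `achieved`, `edge_counts`, and `edges` (the globally sorted
#'   edge index matrix; slice k is its first `edge_counts[k]` rows).
#'   Materialize a slice with [stack_slice()].
#' @export
binarize_stack <- function(fc, grid = sparsity_grid()) {
  n <- nrow(fc)
  ut <- which(upper.tri(fc), arr.ind = TRUE)
  w <- fc[ut]
  pos <- w > 0
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  ord <- order(-w, ut[, 1], ut[, 2])
  edges <- ut[ord, , drop = FALSE]
  m_max <- n * (n - 1) / 2
  dens <- as.numeric(grid)
  counts <- pmin(edge_count_at(dens, n), nrow(edges))
  structure(
    list(
      n = n,
      densities = dens,
      achieved = counts / m_max,
      edge_counts = counts,
      edges = edges,
      labels = colnames(fc)
    ),
    class = "adjacency_stack"
  )
}

#' Extract one binary adjacency slice from a stack
#'
#' @param stack An `adjacency_stack` from [binarize_stack()].
#' @param density A density on the stack's grid (matched with tolerance), or
#'   `index =` to address a slice by position.
#' @param index Optional slice index (overrides `density`).
#' @return An N x N binary symmetric matrix with zero diagonal.
#' @export
stack_slice <- function(stack, density = NULL, index = NULL) {
  if (is.null(index)) {
    index <- which(abs(stack$densities - density) < 1e-9)
    if (length(index) != 1) {
      abort(sprintf("Density %.4g is not on the stack's grid.", density))
    }
  }
  k <- stack$edge_counts[index]
  A <- matrix(0, stack$n, stack$n)
  if (k > 0) {
    e <- stack$edges[seq_len(k), , drop = FALSE]
    A[e] <- 1
    A[e[, c(2, 1), drop = FALSE]] <- 1
  }
  dimnames(A) <- list(stack$labels, stack$labels)
  A
}

#' Binarize at a single density
#'
#' @inheritParams binarize_stack
#' @param density A single density in (0, 1].
#' @return A binary adjacency matrix.
#' @export
binarize_at <- function(fc, density) {
  stack_slice(binarize_stack(fc, density), index = 1L)
}

#' Threshold-range admissibility threshold for the average degree
#'
#' The sparsity range is admissible when the average degree exceeds
#' `2 * log(N)` (natural logarithm: for N = 273 this is 11.22).
#'
#' @param n Number of nodes.
#' @return The degree threshold `2 * log(n)`.
#' @export
admissibility_threshold <- function(n) 2 * log(n)

#' Check the sparsity range on a cohort
#'
#' Reports, per subject-session, the average degree at the sparsest grid
#' density against the `2 log(N)` criterion, and (when small-world curves are
#' supplied) the minimum small-worldness sigma over the grid against the
#' sigma > 1.1 criterion.
#'
#' @param fc_tbl Tibble with columns `subject`, `session`, `fc` (from
#'   [cohort_fc()]).
#' @param grid A [sparsity_grid()].
#' @param sigma_tbl Optional tibble `subject`, `session`, `density`, `value`
#'   of sigma values across the grid (e.g. filtered from metric curves).
#' @param sigma_min Admissibility bound for sigma (default 1.1).
#' @return A tibble with one row per subject-session: minimum-density average
#'   degree, the degree threshold, sigma minimum, and pass/fail flags.
#' @export
admissibility_check <- function(fc_tbl, grid = sparsity_grid(),
                                sigma_tbl = NULL, sigma_min = 1.1) {
  dens_min <- min(as.numeric(grid))
  rows <- purrr::pmap(
    list(fc_tbl$subject, fc_tbl$session, fc_tbl$fc),
    function(subject, session, fc) {
      n <- nrow(fc)
      k <- min(edge_count_at(dens_min, n), sum(fc[upper.tri(fc)] > 0))
      tibble::tibble(
        subject = subject, session = session, n_nodes = n,
        min_density = dens_min,
        avg_degree = 2 * k / n,
        degree_threshold = admissibility_threshold(n),
        degree_pass = 2 * k / n > admissibility_threshold(n)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (!is.null(sigma_tbl)) {
    bound <- sigma_min
    smin <- sigma_tbl |>
      dplyr::group_by(.data$subject, .data$session) |>
      dplyr::summarise(
        sigma_fail_densities = list(.data$density[.data$value <= bound]),
        sigma_min = min(.data$value),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, smin, by = c("subject", "session"))
    out$sigma_pass <- out$sigma_min > sigma_min
  } else {
    out$sigma_min <- NA_real_
    out$sigma_pass <- NA
  }
  out
}
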