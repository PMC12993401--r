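# Independent brute-force oracles. These deliberately avoid every code path
# the package uses (igraph metrics, compiled kernels): Floyd-Warshall for
# distances, matrix-cube triangle counts, path-counting betweenness, direct
# double-sum modularity, 2^n sign-flip enumeration for the signed-rank test.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  D
}

oracle_clustering <- function(A) {
  k <- colSums(A)
  tri <- diag(A %*% A %*% A) / 2
  out <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  as.numeric(out)
}

oracle_lp <- function(A) {
  D <- oracle_distances(A)
  d <- D[row(D) != col(D)]
  if (!any(is.finite(d))) return(NA_real_)
  mean(d[is.finite(d)])
}

oracle_eg <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  d <- D[row(D) != col(D)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

oracle_nodal_eff <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_eloc <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_eg(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# Normalized betweenness via shortest-path counting and the pair-dependency
# formula (not Brandes accumulation).
oracle_betweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  D <- oracle_distances(A)
  # sigma[s, t]: number of shortest s-t paths
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    ds <- D[s, ]
    for (dist in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (w in which(ds == dist)) {
        preds <- which(A[w, ] > 0 & ds == dist - 1)
        sig[s, w] <- sum(sig[s, preds])
      }
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_modularity <- function(A, membership) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- colSums(A)
  expect <- outer(k, k) / m2
  same <- outer(membership, membership, "==")
  sum((A - expect)[same]) / m2
}

oracle_module_counts <- function(A, membership) {
  kk <- max(membership)
  counts <- matrix(0L, kk, kk)
  for (i in seq_len(nrow(A) - 1)) {
    for (j in (i + 1):nrow(A)) {
      if (A[i, j] > 0) {
        a <- min(membership[i], membership[j])
        b <- max(membership[i], membership[j])
        counts[a, b] <- counts[a, b] + 1L
      }
    }
  }
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  counts
}

oracle_participation <- function(A, membership) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    ki <- sum(A[i, ])
    if (ki == 0) return(0)
    s <- 0
    for (m in unique(membership)) {
      kim <- sum(A[i, membership == m])
      s <- s + (kim / ki)^2
    }
    1 - s
  }, numeric(1))
}

# Exhaustive maximum-modularity partition by restricted-growth-string
# enumeration of all set partitions.
oracle_best_partition <- function(A) {
  n <- nrow(A)
  best_q <- -Inf
  best <- NULL
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      q <- oracle_modularity(A, rgs + 1L)
      if (q > best_q) {
        best_q <<- q
        best <<- rgs + 1L
      }
      return(invisible())
    }
    for (v in 0:(maxv + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  recurse(1L, -1L)
  list(membership = best, q = best_q)
}

# Exact signed-rank p by enumerating all 2^n sign assignments (no ties/zeros).
oracle_wilcoxon_exact <- function(d, alternative = "two.sided") {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
}

# Normalized mutual information between two labelings.
oracle_nmi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (i in seq_len(nrow(pij))) {
    for (j in seq_len(ncol(pij))) {
      if (pij[i, j] > 0) {
        mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * pj_[j]))
      }
    }
  }
  hu <- h(pi_); hv <- h(pj_)
  if (hu == 0 && hv == 0) return(1)
  unname(mi / sqrt(hu * hv))
}
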