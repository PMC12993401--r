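test_that("modularity Q matches the definitional double-sum oracle", {
  # two disjoint K4, correct split: Q = 2 (0.5 - 0.25) = 0.5
  A <- adj_two_cliques(4)
  mem <- rep(1:2, each = 4)
  expect_equal(modularity_q(A, mem), 0.5)
  # all nodes in one module: Q = 0
  expect_equal(modularity_q(A, rep(1, 8)), 0)
  # edgeless graph: Q = 0
  expect_equal(modularity_q(adj_empty(5), rep(1, 5)), 0)
  # random graphs and partitions
  for (seed in 1:8) {
    n <- sample(6:15, 1)
    A <- rand_adj(n, 0.35, seed = 300 + seed)
    mem <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_q(A, mem), oracle_modularity(A, mem),
                 tolerance = 1e-12)
    # cross-check against the independent igraph implementation
    if (sum(A) > 0) {
      expect_equal(
        modularity_q(A, mem),
        igraph::modularity(igraph::graph_from_adjacency_matrix(
          A, mode = "undirected"), mem),
        tolerance = 1e-12
      )
    }
  }
})

test_that("community detection recovers clique structure at the exhaustive optimum", {
  # two disjoint K4: components are the optimal modules
  A <- adj_two_cliques(4)
  part <- detect_communities(A)
  expect_equal(part$n_modules, 2)
  expect_equal(part$q, 0.5)
  expect_true(part$nonrandom)
  expect_equal(unname(table(part$membership)), c(4L, 4L), ignore_attr = TRUE)

  # two K5 joined by one bridge: greedy must match exhaustive search
  B <- adj_two_cliques(5, bridge = TRUE)
  pb <- detect_communities(B)
  best <- oracle_best_partition(B)
  expect_equal(pb$q, best$q, tolerance = 1e-12)
  expect_equal(oracle_nmi(pb$membership, best$membership), 1)
  expect_equal(sort(pb$sizes), c(5L, 5L))
})

test_that("greedy Q never exceeds the exhaustive optimum on small graphs", {
  for (seed in 1:6) {
    n <- sample(5:8, 1)
    A <- rand_adj(n, 0.45, seed = 400 + seed)
    if (sum(A) == 0) next
    g_q <- detect_communities(A)$q
    best <- oracle_best_partition(A)
    expect_lte(g_q, best$q + 1e-12)
  }
})

test_that("edgeless graphs give singleton modules with Q = 0", {
  p <- detect_communities(adj_empty(4))
  expect_equal(p$membership, 1:4)
  expect_equal(p$q, 0)
  expect_false(p$nonrandom)
})

test_that("detection is deterministic and tidy/glance expose the partition", {
  A <- rand_adj(40, 0.2, seed = 12)
  p1 <- detect_communities(A)
  p2 <- detect_communities(A)
  expect_identical(p1$membership, p2$membership)
  td <- tidy(p1)
  expect_equal(nrow(td), 40)
  expect_equal(td$module, p1$membership)
  gl <- glance(p1)
  expect_equal(gl$q, p1$q)
  expect_equal(gl$n_modules, p1$n_modules)
})

test_that("planted six-block structure is recovered at high NMI", {
  d <- design_preset("test", "null", seed = 31)
  co <- simulate_cohort(d)
  fc <- cohort_fc(co)
  gg <- group_graph(dplyr::filter(fc, session == "baseline")$fc, 0.15)
  part <- detect_communities(gg)
  expect_gte(oracle_nmi(part$membership, d$partition), 0.9)
  expect_gte(
    igraph::compare(part$membership, d$partition, method = "nmi"), 0.9
  )
})

test_that("group graph is the binarized mean and idempotent for duplicates", {
  set.seed(21)
  fcs <- lapply(1:3, function(i) {
    m <- matrix(0, 12, 12)
    m[upper.tri(m)] <- runif(66)
    m + t(m)
  })
  # one subject: equals that subject's own slice
  expect_equal(group_graph(fcs[1], 0.2), binarize_at(fcs[[1]], 0.2))
  # duplicated matrix changes nothing
  expect_equal(group_graph(list(fcs[[1]], fcs[[1]]), 0.2),
               binarize_at(fcs[[1]], 0.2))
  # general mean
  avg <- (fcs[[1]] + fcs[[2]] + fcs[[3]]) / 3
  expect_equal(group_graph(fcs, 0.2), binarize_at(avg, 0.2))
  expect_error(group_graph(list(fcs[[1]], matrix(0, 5, 5))), "same size")
})

test_that("module edge counts match the brute-force tally and conserve edges", {
  # complete graph, modules of sizes (2, 3): intra 1 and 3, inter 6
  A <- adj_complete(5)
  mem <- c(1, 1, 2, 2, 2)
  cm <- module_edge_counts(A, mem)
  expect_equal(diag(cm), c(1L, 3L))
  expect_equal(cm[1, 2], 6L)
  # empty graph: all-zero matrix
  expect_equal(module_edge_counts(adj_empty(4), c(1, 1, 2, 2)),
               matrix(0L, 2, 2))
  # random graphs vs oracle, plus conservation
  for (seed in 1:6) {
    A <- rand_adj(20, 0.3, seed = 500 + seed)
    mem <- sample(1:3, 20, replace = TRUE)
    mem[1:3] <- 1:3  # ensure every module nonempty
    cm <- module_edge_counts(A, mem)
    expect_equal(cm, oracle_module_counts(A, mem))
    expect_equal(sum(diag(cm)) + sum(cm[upper.tri(cm)]), sum(A) / 2)
  }
  expect_error(module_edge_counts(A, mem[-1]), "do not match")
})

test_that("participation coefficient matches its definition and invariances", {
  # all edges inside the node's own module -> 0
  A <- adj_two_cliques(4)
  mem <- rep(1:2, each = 4)
  expect_equal(participation_coef(A, mem), rep(0, 8))
  # degree-4 node with 2 edges into each of 2 modules -> 0.5
  B <- adj_from_edges(7, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  memb <- c(1, 2, 2, 3, 3, 2, 3)
  expect_equal(participation_coef(B, memb)[1], 0.5)
  # isolated node -> 0
  expect_equal(participation_coef(B, memb)[6], 0)
  for (seed in 1:6) {
    A <- rand_adj(15, 0.3, seed = 600 + seed)
    mem <- sample(1:4, 15, replace = TRUE)
    mem[1:4] <- 1:4
    p <- participation_coef(A, mem)
    expect_equal(p, oracle_participation(A, mem), tolerance = 1e-12)
    # bounded by 1 - 1/K and invariant under module relabeling
    expect_true(all(p <= 1 - 1 / 4 + 1e-12))
    relab <- c(4, 3, 2, 1)[mem]
    expect_equal(participation_coef(A, relab), p)
  }
})

test_that("restricted nodal tables select exactly the implicated modules", {
  part <- structure(
    list(membership = rep(1:3, each = 4), sizes = rep(4L, 3), q = 0.4,
         n_modules = 3L, nonrandom = TRUE, n = 12L),
    class = "modular_partition"
  )
  nv <- tidyr::expand_grid(
    subject = c("S01", "S02"), session = c("baseline", "followup"),
    node = 1:12, metric = "degree"
  )
  nv$value <- seq_len(nrow(nv))
  out <- restricted_nodal_values(nv, part, implicated = c(1, 3))
  expect_setequal(unique(out$node), c(1:4, 9:12))
  expect_setequal(unique(out$module), c(1, 3))
  expect_message(
    empty <- restricted_nodal_values(nv, part, implicated = integer(0)),
    "empty"
  )
  expect_equal(nrow(empty), 0)
})
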