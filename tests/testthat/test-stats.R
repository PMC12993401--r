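test_that("the Shapiro-Wilk gate routes normal and skewed differences correctly", {
  # normal differences keep the t-test in ~95% of seeds
  picks <- vapply(1:200, function(s) {
    set.seed(s)
    normality_gate(rnorm(30))$test == "paired_t"
  }, logical(1))
  expect_gt(mean(picks), 0.90)
  # heavy lognormal skew switches to Wilcoxon nearly always
  picks2 <- vapply(1:200, function(s) {
    set.seed(s)
    normality_gate(exp(rnorm(30, sd = 1.5)))$test == "wilcoxon_signed_rank"
  }, logical(1))
  expect_gt(mean(picks2), 0.95)
  # degenerate: identical differences fall back to Wilcoxon with warning
  expect_warning(g <- normality_gate(rep(2, 10)), "identical")
  expect_equal(g$test, "wilcoxon_signed_rank")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("paired comparisons honour contracts on degenerate and shifted data", {
  x <- rnorm(20)
  # identical sessions: p = 1, no evidence
  res <- paired_test(x, x)
  expect_equal(res$p_raw, 1)
  # shifted copies run and return valid p on both branches
  set.seed(4)
  b <- rnorm(30)
  res2 <- paired_test(b, b + 0.5 + rnorm(30, sd = 0.1), tail = "two_sided")
  expect_true(res2$p_raw >= 0 && res2$p_raw <= 1)
  expect_lt(res2$p_raw, 0.01)
  # one-sided 'greater' with a negative mean difference cannot be small
  set.seed(5)
  b2 <- rnorm(25)
  res3 <- paired_test(b2, b2 - 1 + rnorm(25, sd = 0.2),
                      tail = "one_sided_greater")
  expect_gte(res3$p_raw, 0.5)
  expect_error(paired_test(1:5, 1:4), "aligned")
})

test_that("Wilcoxon branch equals the exact 2^n sign-flip enumeration", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(5:10, 1)
    # lognormal differences so the gate reliably picks Wilcoxon
    d <- exp(rnorm(n, sd = 1.6)) * sign(rnorm(n))
    b <- rnorm(n)
    f <- b + d
    for (tail in c("two_sided", "one_sided_greater", "one_sided_less")) {
      res <- paired_test(b, f, tail = tail)
      if (res$test != "wilcoxon_signed_rank") next
      alt <- c(two_sided = "two.sided", one_sided_greater = "greater",
               one_sided_less = "less")[[tail]]
      expect_equal(res$p_raw, oracle_wilcoxon_exact(d, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches hand-computed step-up examples", {
  expect_equal(fdr_adjust(0.03), 0.03)          # m = 1: unchanged
  # hand oracle: sorted (0.005, 0.03, 0.04) -> (0.015, 0.045, 0.04) ->
  # cummin from top -> (0.015, 0.04, 0.04); restore order
  expect_equal(fdr_adjust(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  set.seed(8)
  p <- runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))                     # adjusted >= raw elementwise
  expect_true(all(adj <= 1))
  # permutation equivariance
  perm <- sample(50)
  expect_equal(fdr_adjust(p[perm]), adj[perm])
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  x <- 1:10
  expect_equal(spearman_cor(x, x * 2 + 3)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  # midrank ties: equals Pearson on midranks
  xt <- c(1, 2, 2, 3, 4, 5)
  yt <- c(2, 1, 4, 4, 6, 5)
  expect_equal(spearman_cor(xt, yt)$rho, cor(rank(xt), rank(yt)))
  expect_warning(res <- spearman_cor(rep(1, 5), 1:5), "Constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_cor(1:3, 1:3), "lengths >= 4")
})

test_that("the statistical plan assembles the families the design implies", {
  d <- design_preset("test", "planted", seed = 41)
  d$n_subjects <- 12L
  co <- simulate_cohort(d)
  fc <- cohort_fc(co)
  grid <- sparsity_grid(0.10, 0.30, 0.10)
  part <- detect_communities(
    group_graph(dplyr::filter(fc, session == "baseline")$fc, 0.15)
  )
  counts <- cohort_module_counts(fc, part, 0.15)
  # per subject-session nodal AUCs (no nulls needed)
  curves <- purrr::map(fc$fc, metric_curves, grid = grid, nulls = NULL,
                       global = FALSE, nodal = TRUE)
  nodal_auc <- purrr::map2_dfr(seq_len(nrow(fc)), curves, function(i, cv) {
    dplyr::bind_cols(fc[i, c("subject", "session")], curve_auc(cv)$nodal)
  })
  partic <- cohort_participation(fc, part, 0.15)
  clin <- simulate_clinical(co)
  plan <- run_statistical_plan(
    global_auc = NULL, nodal_auc = nodal_auc, module_counts = counts,
    participation = partic, partition = part, clinical = clin
  )
  k <- part$n_modules
  expect_equal(nrow(plan$module_inter), k * (k - 1) / 2)  # 15 pairs when K = 6
  expect_equal(nrow(plan$module_intra), k)
  expect_true(all(plan$module_inter$tail == "two_sided"))
  expect_true(all(!is.na(plan$module_inter$p_fdr)))
  # restricted family only contains implicated-module nodes, FDR per metric
  if (!is.null(plan$restricted) && nrow(plan$restricted)) {
    imp_nodes <- which(part$membership %in% plan$implicated_modules$module)
    expect_true(all(plan$restricted$node %in% imp_nodes))
    by_metric <- split(plan$restricted, plan$restricted$metric)
    for (df in by_metric) {
      expect_equal(df$p_fdr, fdr_adjust(df$p_raw))
    }
  }
  # tidy() flattens all families with p-values in range
  td <- tidy(plan)
  expect_true(all(c("family", "item", "p_raw") %in% names(td)))
  expect_true(all(td$p_raw >= 0 & td$p_raw <= 1, na.rm = TRUE))
})

test_that("global tests follow the a priori one-tailed direction table", {
  set.seed(77)
  subs <- sprintf("S%02d", 1:15)
  mets <- c("cp", "lp", "eg", "eloc", "gamma", "lambda", "sigma", "q")
  global_auc <- tidyr::expand_grid(subject = subs,
                                   session = c("baseline", "followup"),
                                   metric = mets)
  global_auc$auc <- rnorm(nrow(global_auc))
  counts <- tidyr::expand_grid(subject = subs,
                               session = c("baseline", "followup"),
                               module_a = 1, module_b = 2)
  counts$type <- "inter"
  counts$count <- rpois(nrow(counts), 10)
  plan <- run_statistical_plan(global_auc, NULL, counts)
  dirs <- plan$directions
  expect_equal(nrow(plan$global), 8)
  for (i in seq_len(nrow(plan$global))) {
    expect_equal(
      plan$global$tail[i],
      dirs$tail[dirs$metric == plan$global$metric[i]]
    )
  }
  expect_true(all(is.na(plan$global$p_fdr)))  # globals are uncorrected
  expect_true(all(c("sigma", "gamma", "cp", "eg", "eloc") %in%
                    dirs$metric[dirs$tail == "one_sided_greater"]))
  expect_true(all(c("lp", "lambda", "q") %in%
                    dirs$metric[dirs$tail == "one_sided_less"]))
})
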