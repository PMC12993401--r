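#' Normality gate for paired differences
#'
#' Shapiro–Wilk on the paired differences decides the paired test: p >= 0.05
#' keeps the paired t-test, p < 0.05 switches to the Wilcoxon signed-rank
#' test. Degenerate samples (all differences identical) cannot be assessed
#' and fall back to Wilcoxon with a warning.
#'
#' @param d Numeric vector of paired differences (length >= 3).
#' @param alpha Gate level (default 0.05).
#' @return A list with `gate_p` (Shapiro–Wilk p, NA when degenerate) and
#'   `test` (`"paired_t"` or `"wilcoxon_signed_rank"`).
#' @export
normality_gate <- function(d, alpha = 0.05) {
  if (length(d) < 3) abort("Need at least 3 paired differences.")
  if (sd(d) == 0) {
    warn("All differences identical; normality cannot be assessed, using Wilcoxon.")
    return(list(gate_p = NA_real_, test = "wilcoxon_signed_rank"))
  }
  p <- shapiro.test(d)$p.value
  list(
    gate_p = p,
    test = if (p >= alpha) "paired_t" else "wilcoxon_signed_rank"
  )
}

tail_to_alternative <- function(tail) {
  switch(tail,
    two_sided = "two.sided",
    one_sided_greater = "greater",
    one_sided_less = "less",
    abort(sprintf("Unknown tail '%s'.", tail))
  )
}

#' Normality-gated paired comparison
#'
#' Compares follow-up against baseline with the test chosen by
#' [normality_gate()] on the differences: a paired t-test, or a Wilcoxon
#' signed-rank test with zero differences dropped (Wilcoxon's convention),
#' exact null distribution for up to 25 tie-free non-zero differences and
#' the continuity-corrected normal approximation otherwise. The tail applies
#' to the difference followup - baseline, so `"one_sided_greater"` tests for
#' an increase at follow-up.
#'
#' @param baseline,followup Subject-aligned numeric vectors (length >= 3).
#' @param tail `"two_sided"`, `"one_sided_greater"` or `"one_sided_less"`.
#' @return One-row tibble: `test`, `statistic`, `p_raw`, `gate_p`, `tail`,
#'   `n`, `n_effective` (after zero-dropping), `mean_diff`. Identical
#'   sessions give p = 1 by contract (no evidence).
#' @export
paired_test <- function(baseline, followup,
                        tail = c("two_sided", "one_sided_greater",
                                 "one_sided_less")) {
  tail <- match.arg(tail)
  if (length(baseline) != length(followup)) {
    abort("baseline and followup must be subject-aligned (equal lengths).")
  }
  if (length(baseline) < 3) abort("Need at least 3 subjects.")
  if (anyNA(baseline) || anyNA(followup)) abort("Values must be finite.")
  d <- followup - baseline
  res <- tibble::tibble(
    test = NA_character_, statistic = NA_real_, p_raw = NA_real_,
    gate_p = NA_real_, tail = tail, n = length(d),
    n_effective = NA_integer_, mean_diff = mean(d)
  )
  if (all(d == 0)) {
    res$test <- "wilcoxon_signed_rank"
    res$statistic <- 0
    res$p_raw <- 1
    res$n_effective <- 0L
    return(res)
  }
  gate <- normality_gate(d)
  res$gate_p <- gate$gate_p
  res$test <- gate$test
  alt <- tail_to_alternative(tail)
  if (gate$test == "paired_t") {
    tt <- t.test(d, mu = 0, alternative = alt)
    res$statistic <- unname(tt$statistic)
    res$p_raw <- tt$p.value
    res$n_effective <- length(d)
  } else {
    dz <- d[d != 0]
    res$n_effective <- length(dz)
    if (length(dz) < 3) {
      warn("Fewer than 3 non-zero differences; Wilcoxon p undefined.")
      return(res)
    }
    exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
    wt <- suppressWarnings(
      wilcox.test(dz, mu = 0, alternative = alt, exact = exact,
                  correct = TRUE)
    )
    res$statistic <- unname(wt$statistic)
    res$p_raw <- wt$p.value
  }
  res
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, q_i = p_i * m / i, enforce
#' monotonicity by cumulative minimum from the largest rank, cap at 1,
#' restore input order.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank-based correlation with midrank ties and a two-sided p-value
#' (t approximation, standard for tied clinical scores).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return One-row tibble `rho`, `p`, `n`; NA with a warning for constant
#'   input.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    abort("Need equal lengths >= 4.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant vector: Spearman correlation undefined.")
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Run gated paired tests for every item of a long table.
# `data`: tibble with columns subject, session, <item cols>, value.
paired_test_table <- function(data, items, tail = "two_sided",
                              tails = NULL, fdr = TRUE, alpha_trend = 0.05) {
  wide <- data |>
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(c("subject", items)),
      names_from = "session", values_from = "value"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(items, "subject"))))
  keys <- dplyr::distinct(wide[, items, drop = FALSE])
  if (nrow(keys) == 0) {
    return(tibble::tibble(
      test = character(0), statistic = numeric(0), p_raw = numeric(0),
      gate_p = numeric(0), tail = character(0), n = integer(0),
      n_effective = integer(0), mean_diff = numeric(0),
      p_fdr = numeric(0), trend = logical(0)
    ))
  }
  rows <- purrr::map(seq_len(nrow(keys)), function(i) {
    sel <- wide
    for (col in items) sel <- sel[sel[[col]] == keys[[col]][i], ]
    this_tail <- if (!is.null(tails)) {
      tails[[as.character(keys[[items[1]]][i])]] %||% tail
    } else {
      tail
    }
    dplyr::bind_cols(
      keys[i, , drop = FALSE],
      paired_test(sel$baseline, sel$followup, tail = this_tail)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (fdr) out$p_fdr <- fdr_adjust(out$p_raw) else out$p_fdr <- NA_real_
  out$trend <- !is.na(out$p_raw) & out$p_raw < alpha_trend
  out
}

#' Run the full paired statistical plan
#'
#' The pipeline's statistical layer: (a) global AUC metrics tested one-tailed
#' and uncorrected, directions fixed a priori (sigma, gamma, Cp, Eg, Eloc
#' expected to increase; Lp, lambda, Q to decrease); (b) whole-brain nodal
#' AUCs two-tailed with BH-FDR across nodes per metric; (c) module-pair edge
#' counts two-tailed, FDR across the inter-module pairs and separately the
#' intra-module families, with uncorrected-0.05 trend flags; (d) a restricted
#' nodal family (degree, nodal efficiency, betweenness AUC, participation)
#' over the modules implicated by the inter-pair trends, FDR scoped per
#' metric to that node set; (e) Spearman correlations of topology changes
#' with clinical improvements and of restricted-significant betweenness
#' changes with trend-pair count changes.
#'
#' @param global_auc Tibble `subject`, `session`, `metric`, `auc`.
#' @param nodal_auc Tibble `subject`, `session`, `node`, `metric`, `auc`.
#' @param module_counts Tibble from [cohort_module_counts()].
#' @param participation Tibble from [cohort_participation()] (may be NULL).
#' @param partition The group `modular_partition`.
#' @param clinical Optional clinical tibble (see [simulate_clinical()]);
#'   when missing, correlations are skipped with a notice.
#' @param alpha_trend Uncorrected trend level (default 0.05).
#' @param alpha_sig Corrected significance level (default 0.05).
#' @return A `stat_plan` list of tibbles: `global`, `nodal`, `module_inter`,
#'   `module_intra`, `implicated_modules`, `restricted`, `correlations`,
#'   plus the a priori `directions` table.
#' @export
run_statistical_plan <- function(global_auc, nodal_auc, module_counts,
                                 participation = NULL, partition = NULL,
                                 clinical = NULL, alpha_trend = 0.05,
                                 alpha_sig = 0.05) {
  dirs <- metric_directions()
  plan <- list()
  plan$directions <- tibble::tibble(
    metric = names(dirs), tail = unname(dirs)
  )

  # (a) global: one-tailed, uncorrected
  plan$global <- NULL
  if (!is.null(global_auc) && nrow(global_auc)) {
    plan$global <- global_auc |>
      dplyr::rename(value = "auc") |>
      paired_test_table(items = "metric", tails = as.list(dirs),
                        fdr = FALSE, alpha_trend = alpha_sig)
  }

  # (b) whole-brain nodal: two-tailed, FDR across nodes per metric
  if (!is.null(nodal_auc) && nrow(nodal_auc)) {
    plan$nodal <- nodal_auc |>
      dplyr::rename(value = "auc") |>
      dplyr::group_by(.data$metric) |>
      dplyr::group_modify(function(df, key) {
        paired_test_table(df, items = "node", tail = "two_sided",
                          alpha_trend = alpha_trend)
      }) |>
      dplyr::ungroup()
  }

  # (c) module-pair counts: FDR separately over inter pairs and intra modules
  counts <- module_counts |>
    dplyr::mutate(
      item = paste0("module", .data$module_a, "&", .data$module_b),
      value = as.numeric(.data$count)
    )
  inter <- dplyr::filter(counts, .data$type == "inter")
  intra <- dplyr::filter(counts, .data$type == "intra")
  key_cols <- c("item", "module_a", "module_b")
  plan$module_inter <- paired_test_table(
    inter, items = key_cols, tail = "two_sided", alpha_trend = alpha_trend
  )
  plan$module_intra <- paired_test_table(
    intra, items = key_cols, tail = "two_sided", alpha_trend = alpha_trend
  )

  # (d) restricted nodal family over implicated modules
  trend_pairs <- dplyr::filter(plan$module_inter, .data$trend)
  implicated <- sort(unique(c(trend_pairs$module_a, trend_pairs$module_b)))
  plan$implicated_modules <- tibble::tibble(module = implicated)
  plan$restricted <- NULL
  has_nodal <- !is.null(nodal_auc) && nrow(nodal_auc) > 0
  if (!is.null(partition) && has_nodal) {
    nodal_values <- nodal_auc |> dplyr::rename(value = "auc")
    if (!is.null(participation) && nrow(participation)) {
      nodal_values <- dplyr::bind_rows(nodal_values, participation)
    }
    restricted <- restricted_nodal_values(nodal_values, partition, implicated)
    if (nrow(restricted)) {
      plan$restricted <- restricted |>
        dplyr::group_by(.data$metric) |>
        dplyr::group_modify(function(df, key) {
          paired_test_table(df, items = c("node", "module"),
                            tail = "two_sided", alpha_trend = alpha_trend)
        }) |>
        dplyr::ungroup()
    } else {
      plan$restricted <- restricted
    }
  }

  # (e) clinical correlations
  plan$correlations <- NULL
  if (is.null(clinical)) {
    inform("No clinical table supplied: Spearman correlations skipped.")
  } else {
    plan$correlations <- plan_correlations(
      plan, global_auc, nodal_auc, counts, clinical, alpha_sig
    )
  }
  structure(plan, class = "stat_plan")
}

# Spearman layer: delta topology vs clinical improvement, and significant
# restricted betweenness deltas vs trend-pair count deltas.
plan_correlations <- function(plan, global_auc, nodal_auc, counts,
                              clinical, alpha_sig) {
  delta_of <- function(df, keys, col = "value") {
    df |>
      tidyr::pivot_wider(
        id_cols = dplyr::all_of(c("subject", keys)),
        names_from = "session", values_from = dplyr::all_of(col)
      ) |>
      dplyr::mutate(delta = .data$followup - .data$baseline)
  }
  clin_long <- clinical |>
    tidyr::pivot_longer(-c("subject", "session"),
                        names_to = "score", values_to = "value")
  # clinical improvement = baseline - followup (scores decrease when better)
  clin_d <- delta_of(clin_long, "score") |>
    dplyr::mutate(improvement = -.data$delta)
  rows <- list()
  glob_d <- if (!is.null(global_auc) && nrow(global_auc)) {
    delta_of(dplyr::rename(global_auc, value = "auc"), "metric")
  } else {
    tibble::tibble(metric = character(0))
  }
  for (met in unique(glob_d$metric)) {
    gd <- dplyr::filter(glob_d, .data$metric == met)
    for (sc in unique(clin_d$score)) {
      cd <- dplyr::filter(clin_d, .data$score == sc)
      joined <- dplyr::inner_join(gd, cd, by = "subject",
                                  suffix = c("_m", "_c"))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(family = "global_vs_clinical",
                       var1 = paste0("delta_", met), var2 = sc),
        spearman_cor(joined$delta_m, joined$improvement)
      )
    }
  }
  # significant restricted betweenness nodes vs trend-pair counts
  if (!is.null(plan$restricted) && nrow(plan$restricted)) {
    sig_bc <- plan$restricted |>
      dplyr::filter(.data$metric == "betweenness",
                    !is.na(.data$p_fdr), .data$p_fdr < alpha_sig)
    trend_items <- dplyr::filter(plan$module_inter, .data$trend)$item
    if (nrow(sig_bc) && length(trend_items)) {
      bc_d <- delta_of(
        dplyr::rename(
          dplyr::filter(nodal_auc, .data$metric == "betweenness"),
          value = "auc"
        ),
        "node"
      )
      cnt_d <- delta_of(
        dplyr::filter(counts, .data$item %in% trend_items), "item"
      )
      for (nd in sig_bc$node) {
        nd_d <- dplyr::filter(bc_d, .data$node == nd)
        for (it in trend_items) {
          id_ <- dplyr::filter(cnt_d, .data$item == it)
          joined <- dplyr::inner_join(nd_d, id_, by = "subject",
                                      suffix = c("_n", "_p"))
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(family = "bc_vs_module_pair",
                           var1 = paste0("delta_bc_node", nd), var2 = it),
            spearman_cor(joined$delta_n, joined$delta_p)
          )
        }
        for (sc in unique(clin_d$score)) {
          cd <- dplyr::filter(clin_d, .data$score == sc)
          joined <- dplyr::inner_join(nd_d, cd, by = "subject",
                                      suffix = c("_n", "_c"))
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(family = "bc_vs_clinical",
                           var1 = paste0("delta_bc_node", nd), var2 = sc),
            spearman_cor(joined$delta_n, joined$improvement)
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.stat_plan <- function(x, ...) {
  cat("<stat_plan>\n")
  if (!is.null(x$global)) {
    cat(sprintf(
      "  global (one-tailed, uncorrected): %d metric(s), %d with p < 0.05\n",
      nrow(x$global), sum(x$global$p_raw < 0.05, na.rm = TRUE)
    ))
  }
  if (!is.null(x$nodal)) {
    cat(sprintf(
      "  nodal (two-tailed, FDR per metric): %d tests, %d FDR-significant\n",
      nrow(x$nodal), sum(x$nodal$p_fdr < 0.05, na.rm = TRUE)
    ))
  }
  cat(sprintf(
    "  module pairs: %d inter (%d trend), %d intra (%d trend)\n",
    nrow(x$module_inter), sum(x$module_inter$trend),
    nrow(x$module_intra), sum(x$module_intra$trend)
  ))
  if (!is.null(x$restricted) && nrow(x$restricted)) {
    cat(sprintf(
      "  restricted nodal family: %d tests over modules {%s}, %d FDR-significant\n",
      nrow(x$restricted),
      paste(x$implicated_modules$module, collapse = ","),
      sum(x$restricted$p_fdr < 0.05, na.rm = TRUE)
    ))
  }
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    cat(sprintf("  correlations: %d Spearman test(s)\n", nrow(x$correlations)))
  }
  invisible(x)
}

#' @rdname run_statistical_plan
#' @param x A `stat_plan`.
#' @param ... Unused.
#' @export
tidy.stat_plan <- function(x, ...) {
  fams <- c("global", "nodal", "module_inter", "module_intra", "restricted")
  out <- purrr::map(fams, function(f) {
    df <- x[[f]]
    if (is.null(df) || !nrow(df)) return(NULL)
    df$family <- f
    item_col <- intersect(c("metric", "item", "node"), names(df))[1]
    df$item <- as.character(df[[item_col]])
    if ("metric" %in% names(df) && item_col != "metric") {
      df$item <- paste(df$metric, df$item, sep = ":")
    } else if (all(c("metric", "node") %in% names(df))) {
      df$item <- paste(df$metric, df$node, sep = ":")
    }
    df[, intersect(
      c("family", "item", "test", "statistic", "p_raw", "p_fdr", "tail",
        "trend", "mean_diff"),
      names(df)
    )]
  })
  dplyr::bind_rows(out)
}
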