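#' Run the full longitudinal network pipeline
#'
#' Orchestrates every stage on a synthetic cohort (or a cohort read from
#' disk): connectivity construction, sparsity-grid binarization and
#' admissibility reporting, global/nodal metric curves with null-model
#' normalization and AUC summaries, group-level community detection at the
#' modular density with module-block edge accounting and participation, the
#' restricted nodal hub analysis, and the paired statistical plan with
#' clinical correlations. Every random draw derives deterministically from
#' `seed`, so the same call reproduces the same report bit-for-bit.
#'
#' @param design A [cohort_design()]; its own seed is overridden by a stream
#'   derived from `seed`. Ignored when `cohort` is supplied.
#' @param cohort Optional pre-built cohort tibble (`subject`, `session`,
#'   `ts`), e.g. from [read_cohort()].
#' @param grid A [sparsity_grid()].
#' @param modular_density Density for the modular analysis (default 0.15).
#' @param nulls A [null_config()] for gamma/lambda/sigma, or `NULL` to skip
#'   small-world normalization.
#' @param seed Master integer seed.
#' @param include_global,include_nodal Toggles for the metric families (the
#'   modular stage only needs `include_nodal`).
#' @param include_q Compute slice-level modularity Q among the global
#'   metrics.
#' @param clinical `TRUE` to simulate clinical scores (synthetic cohorts
#'   only), `FALSE`/`NULL` to skip, or a clinical tibble.
#' @return A `longconn_report` list: `design`, `admissibility`,
#'   `global_auc`, `nodal_auc`, `partition`, `module_counts`,
#'   `participation`, `plan` (the [run_statistical_plan()] bundle), and
#'   `provenance`.
#' @export
run_pipeline <- function(design = design_preset("test", "planted"),
                         cohort = NULL,
                         grid = sparsity_grid(),
                         modular_density = 0.15,
                         nulls = null_config(n_nulls = 20),
                         seed = 1L,
                         include_global = TRUE,
                         include_nodal = TRUE,
                         include_q = TRUE,
                         clinical = TRUE) {
  if (is.null(cohort)) {
    design$seed <- derive_seed(seed, 1L)
    cohort <- simulate_cohort(design)
  }
  fc_tbl <- cohort_fc(cohort)

  curves <- purrr::pmap(
    list(fc_tbl$fc, seq_len(nrow(fc_tbl))),
    function(fc, i) {
      metric_curves(
        fc, grid = grid, nulls = nulls,
        seed = derive_seed(seed, 2L, i),
        global = include_global, nodal = include_nodal,
        include_q = include_q
      )
    }
  )
  aucs <- purrr::map(curves, curve_auc)
  key <- fc_tbl[, c("subject", "session")]
  bind_keyed <- function(parts) {
    dplyr::bind_rows(purrr::map(seq_along(parts), function(i) {
      if (is.null(parts[[i]])) return(NULL)
      dplyr::bind_cols(key[rep(i, nrow(parts[[i]])), ], parts[[i]])
    }))
  }
  global_auc <- bind_keyed(purrr::map(aucs, "global"))
  nodal_auc <- bind_keyed(purrr::map(aucs, "nodal"))

  sigma_tbl <- NULL
  if (include_global && !is.null(nulls)) {
    sigma_tbl <- bind_keyed(purrr::map(curves, function(cv) {
      dplyr::filter(cv$global, .data$metric == "sigma")[, c("density", "value")]
    }))
  }
  admissibility <- admissibility_check(fc_tbl, grid, sigma_tbl = sigma_tbl)

  baseline_fc <- dplyr::filter(fc_tbl, .data$session == "baseline")
  ggraph <- group_graph(baseline_fc$fc, density = modular_density)
  partition <- detect_communities(ggraph)
  module_counts <- cohort_module_counts(fc_tbl, partition, modular_density)
  participation <- cohort_participation(fc_tbl, partition, modular_density)

  clin_tbl <- NULL
  if (isTRUE(clinical)) {
    if (!is.null(attr(cohort, "subjects"))) {
      clin_tbl <- simulate_clinical(cohort, seed = derive_seed(seed, 3L))
    }
  } else if (is.data.frame(clinical)) {
    clin_tbl <- clinical
  }

  plan <- run_statistical_plan(
    global_auc = global_auc,
    nodal_auc = nodal_auc,
    module_counts = module_counts,
    participation = participation,
    partition = partition,
    clinical = clin_tbl
  )

  structure(
    list(
      design = attr(cohort, "design"),
      admissibility = admissibility,
      global_auc = global_auc,
      nodal_auc = nodal_auc,
      partition = partition,
      module_counts = module_counts,
      participation = participation,
      clinical = clin_tbl,
      plan = plan,
      provenance = list(
        seed = as.integer(seed),
        grid = as.numeric(grid),
        modular_density = modular_density,
        nulls = if (is.null(nulls)) NULL else unclass(nulls),
        package_version = as.character(utils::packageVersion("longconn"))
      )
    ),
    class = "longconn_report"
  )
}

#' @export
print.longconn_report <- function(x, ...) {
  cat("<longconn_report>\n")
  if (!is.null(x$design)) {
    cat(sprintf("  cohort: %d subjects x 2 sessions, %d ROIs\n",
                x$design$n_subjects, x$design$n_rois))
  }
  cat(sprintf("  admissibility: %d/%d pass the average-degree criterion\n",
              sum(x$admissibility$degree_pass), nrow(x$admissibility)))
  cat(sprintf("  partition: %d modules, Q = %.3f\n",
              x$partition$n_modules, x$partition$q))
  print(x$plan)
  cat(sprintf("  seed: %d\n", x$provenance$seed))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `longconn_report`.
#' @param ... Unused.
#' @export
glance.longconn_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = if (!is.null(x$design)) x$design$n_subjects else
      dplyr::n_distinct(x$admissibility$subject),
    n_rois = x$partition$n,
    q = x$partition$q,
    n_modules = x$partition$n_modules,
    n_trend_inter_pairs = sum(x$plan$module_inter$trend),
    n_restricted_hits = if (is.null(x$plan$restricted)) 0L else
      sum(x$plan$restricted$p_fdr < 0.05, na.rm = TRUE),
    seed = x$provenance$seed
  )
}

#' @rdname run_pipeline
#' @export
tidy.longconn_report <- function(x, ...) tidy(x$plan)

#' Write a run report's tables to disk
#'
#' Emits plain-text artifacts: CSV tables for every statistical family, the
#' partition as a two-column TSV, the module-count matrices in tidy CSV, the
#' AUC tables, and a JSON run summary with provenance. Re-running with the
#' same report rewrites identical files.
#'
#' @param report A `longconn_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      readr::write_csv(df, file.path(dir, name))
    }
  }
  w(report$admissibility |>
      dplyr::mutate(sigma_fail_densities = NULL), "admissibility.csv")
  w(report$global_auc, "global_auc.csv")
  w(report$nodal_auc, "nodal_auc.csv")
  w(report$module_counts, "module_counts.csv")
  w(report$participation, "participation.csv")
  readr::write_tsv(tidy(report$partition), file.path(dir, "partition.tsv"))
  w(report$plan$global, "tests_global.csv")
  w(report$plan$nodal, "tests_nodal.csv")
  w(report$plan$module_inter, "tests_module_inter.csv")
  w(report$plan$module_intra, "tests_module_intra.csv")
  w(report$plan$restricted, "tests_restricted.csv")
  w(report$plan$correlations, "correlations.csv")
  summary <- list(
    provenance = report$provenance,
    partition = list(
      q = report$partition$q,
      n_modules = report$partition$n_modules,
      sizes = report$partition$sizes
    ),
    implicated_modules = report$plan$implicated_modules$module,
    n_trend_inter_pairs = sum(report$plan$module_inter$trend)
  )
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
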