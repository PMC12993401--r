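test_that("latent correlation has the planted block structure and PSD guarantee", {
  d <- cohort_design(
    n_subjects = 2, n_rois = 30, n_timepoints = 50, modules = 3,
    rho_within = 0.5, rho_between = 0.1,
    effect_pairs = list(c(1, 2)), delta_rho = 0.2, seed = 4
  )
  base <- build_latent_correlation(d, "baseline")
  fol <- build_latent_correlation(d, "followup")
  expect_equal(diag(base), rep(1, 30))
  expect_equal(base, t(base))
  part <- d$partition
  within <- outer(part, part, "==") & upper.tri(base)
  between12 <- outer(part == 1, part == 2, "&")
  between13 <- outer(part == 1, part == 3, "&")
  expect_true(all(abs(base[within] - 0.5) < 1e-9))
  expect_true(all(abs(base[between12] - 0.1) < 1e-9))
  expect_true(all(abs(fol[between12] - 0.3) < 1e-9))   # effect pair boosted
  expect_true(all(abs(fol[between13] - 0.1) < 1e-9))   # untouched pair
  # eigen-decomposition PSD oracle
  expect_gte(min(eigen(fol, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("no planted effect means identical baseline and follow-up matrices", {
  d <- cohort_design(
    n_subjects = 2, n_rois = 20, n_timepoints = 50, modules = 2,
    delta_rho = 0, delta_hub = 0, seed = 1
  )
  expect_identical(build_latent_correlation(d, "baseline"),
                   build_latent_correlation(d, "followup"))
})

test_that("perfect within, zero between gives a block-diagonal matrix of ones", {
  d <- cohort_design(
    n_subjects = 1, n_rois = 8, n_timepoints = 10, modules = 2,
    rho_within = 1, rho_between = 0, seed = 1
  )
  R <- build_latent_correlation(d, "baseline")
  blk <- outer(d$partition, d$partition, "==")
  expect_true(all(R[blk] == 1))
  expect_true(all(R[!blk] == 0))
})

test_that("hub boosts touch only cross-module entries and stay below rho_within", {
  d <- cohort_design(
    n_subjects = 1, n_rois = 24, n_timepoints = 50, modules = 3,
    rho_within = 0.4, rho_between = 0.1,
    hub_rois = c(1L, 2L), delta_hub = 0.5, seed = 2
  )
  fol <- build_latent_correlation(d, "followup")
  part <- d$partition
  cross1 <- which(part != part[1])
  expect_true(all(fol[1, cross1] < 0.4))
  expect_true(all(fol[1, cross1] > 0.1))
  same1 <- setdiff(which(part == part[1]), 1)
  expect_true(all(abs(fol[1, same1] - 0.4) < 0.05)) # PSD projection may nudge
})

test_that("invalid designs are rejected", {
  expect_error(cohort_design(5, 10, 50, modules = c(4, 4)), "sum to n_rois")
  expect_error(
    cohort_design(5, 10, 50, modules = 2, rho_within = 0.2, rho_between = 0.3),
    "rho_between < rho_within"
  )
  expect_error(
    cohort_design(5, 10, 50, modules = 2, effect_pairs = list(c(1, 1))),
    "distinct module"
  )
})

test_that("simulation is deterministic, correctly sized, and seed-sensitive", {
  d <- cohort_design(n_subjects = 5, n_rois = 12, n_timepoints = 20,
                     modules = 2, seed = 99)
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(c1$ts, c2$ts)
  expect_equal(nrow(c1), 10)
  expect_equal(length(unique(c1$subject)), 5)
  expect_true(all(table(c1$subject, c1$session) == 1))
  expect_equal(dim(c1$ts[[1]]), c(20, 12))
  d2 <- d; d2$seed <- 100L
  expect_false(identical(simulate_cohort(d2)$ts[[1]], c1$ts[[1]]))
})

test_that("sample correlations track the latent target at large T", {
  d <- cohort_design(
    n_subjects = 1, n_rois = 24, n_timepoints = 2000, modules = 3,
    rho_within = 0.6, rho_between = 0.1, noise_sd = 0, jitter = 0,
    seed = 11
  )
  co <- simulate_cohort(d)
  r <- cor(co$ts[[1]])
  within <- outer(d$partition, d$partition, "==") & upper.tri(r)
  between <- !outer(d$partition, d$partition, "==") & upper.tri(r)
  expect_lt(abs(mean(r[within]) - 0.6), 0.05)
  expect_lt(abs(mean(r[between]) - 0.1), 0.05)
})

test_that("observation noise attenuates correlations by 1/(1+noise_sd^2)", {
  d <- cohort_design(
    n_subjects = 1, n_rois = 16, n_timepoints = 4000, modules = 2,
    rho_within = 0.5, rho_between = 0.1, noise_sd = 0.5, jitter = 0,
    seed = 12
  )
  co <- simulate_cohort(d)
  r <- cor(co$ts[[1]])
  within <- outer(d$partition, d$partition, "==") & upper.tri(r)
  expect_lt(abs(mean(r[within]) - 0.5 / 1.25), 0.05)
})

test_that("cohorts round-trip through the TSV writer and reader", {
  d <- cohort_design(n_subjects = 3, n_rois = 10, n_timepoints = 15,
                     modules = c(7L, 3L), seed = 5)
  co <- simulate_cohort(d)
  atlas <- design_atlas(d)
  dir <- withr::local_tempdir()
  write_cohort(co, atlas, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$cohort), 6)           # manifest rows = 2 x subjects
  expect_equal(back$seed, d$seed)
  for (i in seq_len(nrow(co))) {
    expect_equal(back$cohort$ts[[i]], co$ts[[i]], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(attr(back$atlas, "n_rois"), 10)
})

test_that("a 246 + 27 atlas is read back as 273 ROIs", {
  atlas <- atlas_spec(246, 27)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_equal(attr(back, "n_rois"), 273)
  expect_equal(attr(back, "n_cerebral"), 246)
  expect_equal(attr(back, "n_cerebellar"), 27)
})

test_that("clinical scores improve on the treated side and track effect scale", {
  d <- design_preset("test", "planted", seed = 21)
  co <- simulate_cohort(d)
  clin <- simulate_clinical(co)
  wide <- tidyr::pivot_wider(clin, names_from = session,
                             values_from = dplyr::starts_with("ftm"))
  imp <- with(wide, (ftm_ab_treated_baseline - ftm_ab_treated_followup) /
                ftm_ab_treated_baseline)
  expect_true(mean(imp) > 0.4 && mean(imp) < 0.9)
  # untreated side roughly stable
  d_un <- with(wide, ftm_ab_untreated_followup - ftm_ab_untreated_baseline)
  expect_lt(abs(mean(d_un)), 2)
  # coupling with the per-subject effect scale
  u <- attr(co, "subjects")$effect_scale
  expect_gt(cor(u, imp, method = "spearman"), 0.3)
})
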