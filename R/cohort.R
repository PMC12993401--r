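#' Describe a synthetic paired cohort
#'
#' A cohort design fixes everything the synthetic generator needs to produce a
#' paired (baseline / follow-up) cohort of ROI time series with known ground
#' truth: a planted modular correlation structure, designated hub ROIs, and a
#' planted follow-up effect. Correlations inside a module sit at `rho_within`,
#' correlations between modules at `rho_between`; at follow-up the module
#' pairs in `effect_pairs` gain `delta_rho` and the cross-module couplings of
#' `hub_rois` gain `delta_hub` (capped strictly below `rho_within`).
#'
#' @param n_subjects Number of subjects (each contributes two sessions).
#' @param n_rois Number of ROIs.
#' @param n_timepoints Time points per scan (T, rows of a time-series matrix).
#' @param modules Either an integer K (modules of near-equal size) or an
#'   integer vector of module sizes summing to `n_rois`.
#' @param rho_within Latent correlation inside modules, in (0, 1].
#' @param rho_between Latent correlation between modules, `0 <= rho_between <
#'   rho_within`.
#' @param effect_pairs List of length-2 integer vectors: module pairs whose
#'   between-module coupling increases by `delta_rho` at follow-up.
#' @param delta_rho Follow-up increase in coupling for `effect_pairs`.
#' @param hub_rois Integer ROI indices whose cross-module couplings increase
#'   by `delta_hub` at follow-up.
#' @param delta_hub Follow-up increase for hub cross-module couplings.
#' @param noise_sd Observation noise scale; the sampling covariance is the
#'   latent correlation plus `noise_sd^2` on the diagonal, so observed
#'   correlations are attenuated by `1 / (1 + noise_sd^2)`.
#' @param jitter Half-width of the uniform per-subject jitter applied to
#'   `rho_within` and `rho_between` (subjects differ, sessions of one subject
#'   share the jitter).
#' @param seed Integer RNG seed; the single source of randomness.
#' @return An object of class `cohort_design` (a named list).
#' @seealso [design_preset()], [simulate_cohort()], [build_latent_correlation()]
#' @export
cohort_design <- function(n_subjects,
                          n_rois,
                          n_timepoints,
                          modules,
                          rho_within = 0.35,
                          rho_between = 0.10,
                          effect_pairs = list(),
                          delta_rho = 0,
                          hub_rois = integer(),
                          delta_hub = 0,
                          noise_sd = 0.3,
                          jitter = 0.03,
                          seed = 1L) {
  if (n_subjects < 1 || n_rois < 2 || n_timepoints < 2) {
    abort("Need n_subjects >= 1, n_rois >= 2 and n_timepoints >= 2.")
  }
  if (length(modules) == 1L) {
    k <- as.integer(modules)
    base <- n_rois %/% k
    sizes <- rep(base, k)
    extra <- n_rois - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  } else {
    sizes <- as.integer(modules)
  }
  if (any(sizes < 1L) || sum(sizes) != n_rois) {
    abort("Module sizes must be positive and sum to n_rois.")
  }
  if (!(rho_between >= 0 && rho_between < rho_within && rho_within <= 1)) {
    abort("Require 0 <= rho_between < rho_within <= 1.")
  }
  partition <- rep(seq_along(sizes), sizes)
  k <- length(sizes)
  for (pr in effect_pairs) {
    if (length(pr) != 2 || any(pr < 1) || any(pr > k) || pr[1] == pr[2]) {
      abort("Each effect pair must name two distinct module ids.")
    }
  }
  hub_rois <- as.integer(hub_rois)
  if (length(hub_rois) && (any(hub_rois < 1) || any(hub_rois > n_rois))) {
    abort("hub_rois must be valid ROI indices.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_rois = as.integer(n_rois),
      n_timepoints = as.integer(n_timepoints),
      module_sizes = sizes,
      partition = partition,
      rho_within = rho_within,
      rho_between = rho_between,
      effect_pairs = effect_pairs,
      delta_rho = delta_rho,
      hub_rois = hub_rois,
      delta_hub = delta_hub,
      noise_sd = noise_sd,
      jitter = jitter,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %d subjects x 2 sessions, %d ROIs (%d modules), T = %d\n",
    x$n_subjects, x$n_rois, length(x$module_sizes), x$n_timepoints
  ))
  cat(sprintf(
    "  rho within/between = %.2f / %.2f, noise_sd = %.2f, jitter = %.2f, seed = %d\n",
    x$rho_within, x$rho_between, x$noise_sd, x$jitter, x$seed
  ))
  if (length(x$effect_pairs)) {
    cat(sprintf(
      "  follow-up effect: +%.2f on module pairs {%s}; +%.2f on %d hub ROI(s)\n",
      x$delta_rho,
      paste(vapply(x$effect_pairs, paste, "", collapse = "-"), collapse = ", "),
      x$delta_hub, length(x$hub_rois)
    ))
  } else {
    cat("  no planted follow-up effect (null design)\n")
  }
  invisible(x)
}

#' Preset cohort designs
#'
#' Two scales are provided: `"test"` — 20 subjects, 90 ROIs in 6 modules of
#' 15, 150 time points (desk-scale, used throughout the test-suite
#' simulations); `"full"` — 37 subjects, 273 ROIs in 6 modules of sizes
#' 31/33/77/18/69/45, 250 time points (the full study emulation). The
#' `"planted"` effect raises coupling between module pairs (2,4) and (2,6) by
#' 0.15 and boosts the cross-module coupling of three hub ROIs in module 2 by
#' 0.12; `"null"` plants no effect, making the two sessions exchangeable.
#'
#' @param scale `"test"` or `"full"`.
#' @param effect `"planted"` or `"null"`.
#' @param seed Integer RNG seed.
#' @return A [cohort_design()].
#' @export
design_preset <- function(scale = c("test", "full"),
                          effect = c("planted", "null"),
                          seed = 1L) {
  scale <- match.arg(scale)
  effect <- match.arg(effect)
  if (scale == "test") {
    sizes <- rep(15L, 6)
    n_sub <- 20L; tt <- 150L
  } else {
    sizes <- c(31L, 33L, 77L, 18L, 69L, 45L)
    n_sub <- 37L; tt <- 250L
  }
  mod2 <- which(rep(seq_along(sizes), sizes) == 2L)
  planted <- effect == "planted"
  cohort_design(
    n_subjects = n_sub,
    n_rois = sum(sizes),
    n_timepoints = tt,
    modules = sizes,
    effect_pairs = if (planted) list(c(2L, 4L), c(2L, 6L)) else list(),
    delta_rho = if (planted) 0.15 else 0,
    hub_rois = if (planted) mod2[1:3] else integer(),
    delta_hub = if (planted) 0.12 else 0,
    seed = seed
  )
}

#' Atlas matching a cohort design
#'
#' The last module of the design is treated as the cerebellar block (the
#' presets place the cerebellum in module 6); all other ROIs are cerebral.
#'
#' @param design A [cohort_design()].
#' @return An atlas tibble, as from [atlas_spec()].
#' @export
design_atlas <- function(design) {
  n_cbl <- design$module_sizes[length(design$module_sizes)]
  atlas_spec(design$n_rois - n_cbl, n_cbl, labels = roi_labels(design))
}

roi_labels <- function(design) {
  w <- max(3L, nchar(as.character(design$n_rois)))
  sprintf(paste0("ROI_%0", w, "d"), seq_len(design$n_rois))
}

# Latent correlation for given rho levels and (possibly scaled) effects.
latent_correlation <- function(design, session, rho_w, rho_b,
                               delta_rho, delta_hub) {
  n <- design$n_rois
  part <- design$partition
  same <- outer(part, part, "==")
  R <- matrix(rho_b, n, n)
  R[same] <- rho_w
  if (session == "followup") {
    for (pr in design$effect_pairs) {
      idx <- outer(part == pr[1], part == pr[2], "&") |
        outer(part == pr[2], part == pr[1], "&")
      R[idx] <- R[idx] + delta_rho
    }
    if (length(design$hub_rois) && delta_hub != 0) {
      cap <- rho_w * (1 - 1e-6)
      for (h in design$hub_rois) {
        cross <- part != part[h]
        R[h, cross] <- pmin(R[h, cross] + delta_hub, cap)
        R[cross, h] <- R[h, cross]
      }
    }
  }
  diag(R) <- 1
  R <- (R + t(R)) / 2
  R <- psd_project(R)
  R
}

# Nearest-PSD by eigenvalue clipping at zero, then rescale to unit diagonal.
psd_project <- function(R, tol = 1e-10) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= -tol) return(R)
  vals <- pmax(ev$values, 0)
  R2 <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  R2 <- (R2 + t(R2)) / 2
  diag(R2) <- 1
  if (min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) < -tol) {
    abort("Internal failure: latent matrix not PSD after projection.")
  }
  R2
}

#' Latent correlation matrix of a design
#'
#' Returns the design-level (un-jittered) latent correlation matrix for one
#' session: `rho_within` inside modules, `rho_between` between, with the
#' planted follow-up effects applied for `session = "followup"` and the
#' result projected to the nearest positive semi-definite correlation matrix
#' if needed.
#'
#' @param design A [cohort_design()].
#' @param session `"baseline"` or `"followup"`.
#' @return An `n_rois` x `n_rois` correlation matrix.
#' @export
build_latent_correlation <- function(design,
                                     session = c("baseline", "followup")) {
  session <- match.arg(session)
  latent_correlation(design, session, design$rho_within, design$rho_between,
                     design$delta_rho, design$delta_hub)
}

#' Simulate a paired cohort of ROI time series
#'
#' Each subject contributes a baseline and a follow-up session, drawn as
#' `n_timepoints` independent multivariate-normal samples under the subject's
#' session-specific latent correlation plus `noise_sd^2` diagonal inflation.
#' Subjects receive (i) a uniform jitter of `±jitter` on both rho levels,
#' shared by their two sessions, and (ii) an effect-size scale drawn from
#' Unif(0.7, 1.3) multiplying `delta_rho` and `delta_hub` — the same scale
#' later drives the synthetic clinical improvement, so clinical-topology
#' correlations have a planted signal. Output is deterministic given
#' `design$seed`.
#'
#' @param design A [cohort_design()].
#' @return A tibble with one row per subject-session and columns `subject`,
#'   `session` (`"baseline"`/`"followup"`) and `ts` (list column of T x N
#'   matrices with ROI-labelled columns). The per-subject jitters and effect
#'   scales are attached as attribute `"subjects"`; the design as `"design"`.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$n_timepoints < 2) abort("Need at least 2 time points.")
  n <- design$n_rois
  labs <- roi_labels(design)
  subj_ids <- sprintf("S%02d", seq_len(design$n_subjects))
  with_seed(design$seed, {
    rows <- vector("list", 2L * design$n_subjects)
    subj_tbl <- vector("list", design$n_subjects)
    r <- 0L
    for (i in seq_len(design$n_subjects)) {
      jw <- runif(1, -design$jitter, design$jitter)
      jb <- runif(1, -design$jitter, design$jitter)
      u <- runif(1, 0.7, 1.3)
      rho_w <- min(max(design$rho_within + jw, 0.01), 1)
      rho_b <- min(max(design$rho_between + jb, 0), rho_w - 0.01)
      subj_tbl[[i]] <- tibble::tibble(
        subject = subj_ids[i], jitter_within = jw, jitter_between = jb,
        effect_scale = u
      )
      for (session in c("baseline", "followup")) {
        R <- latent_correlation(design, session, rho_w, rho_b,
                                design$delta_rho * u, design$delta_hub * u)
        sigma <- R
        diag(sigma) <- diag(sigma) + design$noise_sd^2
        L <- chol(sigma)
        Z <- matrix(rnorm(design$n_timepoints * n), design$n_timepoints, n)
        X <- Z %*% L
        colnames(X) <- labs
        r <- r + 1L
        rows[[r]] <- tibble::tibble(
          subject = subj_ids[i], session = session, ts = list(X)
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "design") <- design
    attr(out, "subjects") <- dplyr::bind_rows(subj_tbl)
    out
  })
}

#' Simulate clinical tremor scores for a cohort
#'
#' Emulates a tremor rating scale (treated-side A/B, untreated-side A/B, and
#' part C) for the subjects of a simulated cohort. The treated side improves
#' by ~65% on average (per-subject percent improvement, then averaged), part C
#' by ~67%, and the untreated side is stable. Each subject's improvement is
#' coupled to the effect-size scale drawn in [simulate_cohort()], so cohorts
#' with a planted network effect carry a real clinical-topology association.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param seed Optional seed; defaults to a stream derived from the design
#'   seed.
#' @return A tibble `subject`, `session`, `ftm_ab_treated`,
#'   `ftm_ab_untreated`, `ftm_c`.
#' @export
simulate_clinical <- function(cohort, seed = NULL) {
  design <- attr(cohort, "design")
  subjects <- attr(cohort, "subjects")
  if (is.null(design) || is.null(subjects)) {
    abort("`cohort` must come from simulate_cohort() (missing attributes).")
  }
  seed <- seed %||% derive_seed(design$seed, 9001L)
  with_seed(seed, {
    n <- nrow(subjects)
    base_tr <- pmax(rnorm(n, 18.3, 5.5), 4)
    base_un <- pmax(rnorm(n, 16.1, 6.3), 3)
    base_c <- pmax(rnorm(n, 16.5, 4.2), 3)
    u <- subjects$effect_scale
    imp_tr <- pmin(pmax(0.654 * (0.5 + 0.5 * u) + rnorm(n, 0, 0.06), 0.05), 0.95)
    imp_c <- pmin(pmax(0.670 * (0.5 + 0.5 * u) + rnorm(n, 0, 0.06), 0.05), 0.95)
    fol_un <- pmax(base_un + rnorm(n, 0, 1.5), 0)
    tibble::tibble(
      subject = rep(subjects$subject, each = 2L),
      session = rep(c("baseline", "followup"), times = n),
      ftm_ab_treated = as.vector(rbind(base_tr, base_tr * (1 - imp_tr))),
      ftm_ab_untreated = as.vector(rbind(base_un, fol_un)),
      ftm_c = as.vector(rbind(base_c, base_c * (1 - imp_c)))
    )
  })
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` stores one TSV matrix per subject-session (header row =
#' ROI labels), an atlas table, and a manifest recording subject, session,
#' relative path and the design seed. `read_cohort()` inverts it; the
#' round-trip is lossless to text-serialization precision.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (or the same shape).
#' @param atlas An atlas tibble whose labels match the time-series columns.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()`: the manifest path, invisibly. `read_cohort()`:
#'   a list with elements `cohort` (tibble like [simulate_cohort()] output),
#'   `atlas`, and `seed`.
#' @export
write_cohort <- function(cohort, atlas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labs <- colnames(cohort$ts[[1]])
  if (!identical(labs, atlas$roi_label)) {
    abort("Atlas labels do not match the time-series columns.")
  }
  design <- attr(cohort, "design")
  seed <- if (!is.null(design)) design$seed else NA_integer_
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    if (!identical(colnames(cohort$ts[[i]]), labs)) {
      abort("All time-series matrices must share the same ROI columns.")
    }
    fn <- sprintf("%s_%s.tsv", cohort$subject[i], cohort$session[i])
    readr::write_tsv(
      tibble::as_tibble(cohort$ts[[i]], .name_repair = "minimal"),
      file.path(dir, fn)
    )
    paths[i] <- fn
  }
  manifest <- tibble::tibble(
    subject = cohort$subject, session = cohort$session,
    path = paths, seed = seed
  )
  write_atlas(atlas, file.path(dir, "atlas.tsv"))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_tsv(
    file.path(dir, "manifest.tsv"),
    col_types = readr::cols(
      subject = readr::col_character(), session = readr::col_character(),
      path = readr::col_character(), seed = readr::col_integer()
    )
  )
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  ts <- lapply(manifest$path, function(p) {
    m <- as.matrix(readr::read_tsv(
      file.path(dir, p),
      col_types = readr::cols(.default = readr::col_double())
    ))
    if (!identical(colnames(m), atlas$roi_label)) {
      abort(sprintf("Columns of %s do not match the atlas labels.", p))
    }
    m
  })
  cohort <- tibble::tibble(
    subject = manifest$subject, session = manifest$session, ts = ts
  )
  list(cohort = cohort, atlas = atlas, seed = manifest$seed[1])
}
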