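# Synthetic cohorts with the statistical structure the SCN pipeline assumes:
# multivariate-normal ROI values with block correlation structure, linear
# age and intracranial-volume confounds, and plantable group or longitudinal
# covariance differences. Defaults emulate the shape of a late-middle-aged
# oncology cohort (age ~ N(59.7, 9.38) years, ICV ~ N(1.45e6, 1.4e5) mm^3,
# subcortical volumes of a few thousand mm^3).

#' Specification of one synthetic group
#'
#' Describes a group of subjects whose ROI values are drawn from a
#' multivariate normal with a block-structured correlation matrix
#' (within-block correlation `r`, background correlation `r0`), plus linear
#' age and ICV effects and optional independent measurement noise.
#'
#' @param atlas Atlas identifier (see [atlases()]) or `atlas_spec`.
#' @param n_subjects Number of subjects.
#' @param group_label Group label stored in the cohort.
#' @param blocks List of `list(nodes = <integer indices>, r = <within-block
#'   correlation>)`; blocks must not overlap and each `r` must satisfy
#'   `r0 <= r < 1`.
#' @param r0 Background correlation between all other ROI pairs.
#' @param roi_mean,roi_sd Marginal mean and SD of the ROI measure (mm^3 for
#'   volumes).
#' @param beta_age Effect of age (units of measure per year; scalar or
#'   per-ROI vector). Negative values emulate atrophy.
#' @param beta_icv Effect of ICV (units per mm^3; scalar or per-ROI).
#' @param age_mean,age_sd,icv_mean,icv_sd Covariate distributions.
#' @param noise_sd SD of independent measurement noise added on top of the
#'   correlated component (attenuates correlations by
#'   `roi_sd^2 / (roi_sd^2 + noise_sd^2)`); default 0.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(atlas = "subcortical17", n_subjects = 40,
                           group_label = "G", blocks = list(), r0 = 0.1,
                           roi_mean = 4500, roi_sd = 450,
                           beta_age = -15, beta_icv = 0.003,
                           age_mean = 59.7, age_sd = 9.38,
                           icv_mean = 1.45e6, icv_sd = 1.4e5,
                           noise_sd = 0, seed = 1) {
  if (!inherits(atlas, "atlas_spec")) atlas <- load_atlas(atlas)
  p <- atlas$n_nodes
  used <- integer(0)
  for (b in blocks) {
    stopifnot(is.numeric(b$nodes), is.numeric(b$r), length(b$r) == 1L)
    if (any(b$nodes < 1 | b$nodes > p)) {
      stop("block node index outside 1..", p, call. = FALSE)
    }
    if (length(intersect(used, b$nodes)) > 0L) {
      stop("blocks overlap", call. = FALSE)
    }
    if (!(b$r >= r0 && b$r < 1)) {
      stop("block correlation must satisfy r0 <= r < 1", call. = FALSE)
    }
    used <- c(used, b$nodes)
  }
  if (!(r0 >= 0 && r0 < 1)) stop("r0 must be in [0, 1)", call. = FALSE)
  C <- .block_correlation(p, blocks, r0)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("implied correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", signif(min(ev), 4), ")", call. = FALSE)
  }
  structure(list(atlas = atlas, n_subjects = n_subjects,
                 group_label = group_label, blocks = blocks, r0 = r0,
                 correlation = C,
                 roi_mean = roi_mean, roi_sd = roi_sd,
                 beta_age = rep_len(beta_age, p),
                 beta_icv = rep_len(beta_icv, p),
                 age_mean = age_mean, age_sd = age_sd,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_spec")
}

.block_correlation <- function(p, blocks, r0) {
  C <- matrix(r0, p, p)
  for (b in blocks) C[b$nodes, b$nodes] <- b$r
  diag(C) <- 1
  C
}

#' Generate a synthetic cohort
#'
#' Draws ages, intracranial volumes and correlated ROI values from a
#' [synthetic_spec()]; deterministic for a fixed `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @return A `cohort` (see [assemble_cohort()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  p <- spec$atlas$n_nodes
  age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
  icv <- stats::rnorm(n, spec$icv_mean, spec$icv_sd)
  Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = spec$correlation)
  Y <- spec$roi_mean + spec$roi_sd * Z +
    outer(age, spec$beta_age) + outer(icv, spec$beta_icv)
  if (spec$noise_sd > 0) {
    Y <- Y + matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
  }
  ids <- sprintf("%s_%03d", spec$group_label, seq_len(n))
  dimnames(Y) <- list(ids, spec$atlas$roi_names)
  subjects <- data.frame(subject_id = ids, group = spec$group_label,
                         age = age, icv = icv, stringsAsFactors = FALSE)
  structure(list(subjects = subjects, values = Y,
                 measure_kind = "volume", atlas = spec$atlas),
            class = "cohort")
}

#' Generate two independent cohorts differing only as specified
#'
#' @param specA,specB Two [synthetic_spec()]s sharing the atlas and
#'   covariate model; they may differ in block correlations (a planted
#'   group difference), sample size, label and seed.
#' @return List with cohorts `A` and `B`.
#' @export
make_group_pair <- function(specA, specB) {
  stopifnot(inherits(specA, "synthetic_spec"),
            inherits(specB, "synthetic_spec"))
  if (specA$atlas$name != specB$atlas$name) {
    stop("specs use different atlases", call. = FALSE)
  }
  same_cov <- isTRUE(all.equal(
    specA[c("beta_age", "beta_icv", "age_mean", "age_sd",
            "icv_mean", "icv_sd")],
    specB[c("beta_age", "beta_icv", "age_mean", "age_sd",
            "icv_mean", "icv_sd")]))
  if (!same_cov) {
    stop("specs must share the covariate model", call. = FALSE)
  }
  if (specA$group_label == specB$group_label) {
    stop("group labels must differ", call. = FALSE)
  }
  list(A = generate_cohort(specA), B = generate_cohort(specB))
}

#' Generate a paired (longitudinal) synthetic cohort
#'
#' Each of `n_pairs` subjects contributes two scans. Scan-1 values follow
#' the base correlation structure; scan-2 values are correlated with scan 1
#' at `rho_within_subject` per ROI and follow a correlation structure whose
#' block correlations are shifted by `effect` (negative values emulate a
#' loss of covariance at follow-up). The scan-2 structure is matched
#' exactly: the innovation covariance (C2 - rho^2 C1) / (1 - rho^2) must be
#' positive semi-definite, otherwise the requested effect/rho combination is
#' rejected.
#'
#' @param n_pairs Number of subject pairs.
#' @param effect Additive shift of every block correlation at scan 2 (or a
#'   vector, one per block).
#' @param rho_within_subject Within-subject correlation between scans, in
#'   \[0, 1).
#' @param seed Integer seed.
#' @param spec Base [synthetic_spec()] supplying atlas, blocks and covariate
#'   model (its `n_subjects`/`seed` are ignored).
#' @param scan_interval_mean,scan_interval_sd Years between scans (ages at
#'   scan 2 are shifted accordingly).
#' @return A `cohort` with `pair_id` and group levels `"scan1"`/`"scan2"`.
#' @export
make_paired_cohort <- function(n_pairs = 8, effect = -0.3,
                               rho_within_subject = 0.8, seed = 1,
                               spec = synthetic_spec(),
                               scan_interval_mean = 0.33,
                               scan_interval_sd = 0.17) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!(rho_within_subject >= 0 && rho_within_subject < 1)) {
    stop("rho_within_subject must be in [0, 1)", call. = FALSE)
  }
  p <- spec$atlas$n_nodes
  shifts <- rep_len(effect, length(spec$blocks))
  blocks2 <- spec$blocks
  for (i in seq_along(blocks2)) {
    r2 <- blocks2[[i]]$r + shifts[i]
    if (!(r2 >= 0 && r2 < 1)) {
      stop("invalid correlation target: block ", i, " would have r = ", r2,
           call. = FALSE)
    }
    blocks2[[i]]$r <- r2
  }
  C1 <- spec$correlation
  C2 <- .block_correlation(p, blocks2, spec$r0)
  rho <- rho_within_subject
  Ce <- (C2 - rho^2 * C1) / (1 - rho^2)
  ev <- eigen(Ce, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("invalid correlation target: innovation covariance not positive ",
         "semi-definite (smallest eigenvalue ", signif(min(ev), 4), ")",
         call. = FALSE)
  }
  set.seed(seed)
  n <- n_pairs
  age1 <- stats::rnorm(n, spec$age_mean, spec$age_sd)
  interval <- pmax(0, stats::rnorm(n, scan_interval_mean, scan_interval_sd))
  icv <- stats::rnorm(n, spec$icv_mean, spec$icv_sd)
  Z1 <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = C1)
  E <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Ce)
  if (n == 1L) { Z1 <- matrix(Z1, 1L); E <- matrix(E, 1L) }
  Z2 <- rho * Z1 + sqrt(1 - rho^2) * E
  mk <- function(Z, age) spec$roi_mean + spec$roi_sd * Z +
    outer(age, spec$beta_age) + outer(icv, spec$beta_icv)
  Y1 <- mk(Z1, age1)
  Y2 <- mk(Z2, age1 + interval)
  pair_id <- sprintf("P%03d", seq_len(n))
  ids <- c(paste0(pair_id, "_s1"), paste0(pair_id, "_s2"))
  Y <- rbind(Y1, Y2)
  dimnames(Y) <- list(ids, spec$atlas$roi_names)
  subjects <- data.frame(
    subject_id = ids,
    group = rep(c("scan1", "scan2"), each = n),
    age = c(age1, age1 + interval),
    icv = c(icv, icv),
    pair_id = c(pair_id, pair_id),
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, values = Y,
                 measure_kind = "volume", atlas = spec$atlas),
            class = "cohort")
}

# Block layout used by the packaged 17-node fixtures: anatomically grouped
# covariance blocks (basal ganglia, amygdalo-hippocampal, thalamic,
# cingulate) over the subcortical17 node order.
.fixture_blocks_17 <- function(r_strong) {
  list(list(nodes = 3:8, r = r_strong),    # caudate/putamen/pallidum L+R
       list(nodes = 9:12, r = r_strong),   # hippocampus/amygdala L+R
       list(nodes = 1:2, r = r_strong),    # thalamus L+R
       list(nodes = 13:17, r = r_strong))  # cingulate subdivisions
}

#' Packaged synthetic fixtures
#'
#' Seeded, fast-to-generate scenarios used throughout the test-suite and
#' the analysis scripts:
#'
#' * `"null_17"` — two groups from the identical generator (block r = 0.5)
#'   on the subcortical17 atlas: the type-I-error scenario.
#' * `"effect_17"` — group A with strong block covariance (r = 0.7), group B
#'   with the structure collapsed to background (r = 0.1): the power
#'   scenario.
#' * `"paired_8"` — 8 subject pairs whose follow-up scan loses 0.35 of the
#'   within-block correlation in the amygdalo-hippocampal block at
#'   within-subject correlation 0.8: the longitudinal scenario, small
#'   enough for exhaustive sign enumeration. At this sample size a
#'   covariance statistic has essentially no power; the fixture exercises
#'   the exact-enumeration machinery.
#' * `"paired_23"` — 23 pairs (the size of a typical follow-up subsample)
#'   losing about 0.5 of every block correlation at within-subject
#'   correlation 0.5: the longitudinal power scenario.
#'
#' @param name Fixture identifier.
#' @param n_per_group Subjects per group (pairs for the paired fixtures);
#'   `NULL` uses the fixture default (40 per group / 8 or 23 pairs).
#' @param seed Integer seed; group B uses a derived independent stream.
#' @return For the two-group fixtures, `list(A =, B =)` of `cohort`s; for
#'   `"paired_8"`, a paired `cohort`.
#' @export
fixture_cohort <- function(name = c("null_17", "effect_17", "paired_8",
                                    "paired_23"),
                           n_per_group = NULL, seed = 1) {
  name <- match.arg(name)
  seedB <- (seed + 1000003L) %% .Machine$integer.max
  if (name == "null_17") {
    n <- if (is.null(n_per_group)) 40 else n_per_group
    blocks <- .fixture_blocks_17(0.5)
    make_group_pair(
      synthetic_spec(n_subjects = n, group_label = "A", blocks = blocks,
                     r0 = 0.1, seed = seed),
      synthetic_spec(n_subjects = n, group_label = "B", blocks = blocks,
                     r0 = 0.1, seed = seedB))
  } else if (name == "effect_17") {
    n <- if (is.null(n_per_group)) 40 else n_per_group
    make_group_pair(
      synthetic_spec(n_subjects = n, group_label = "A",
                     blocks = .fixture_blocks_17(0.7), r0 = 0.1,
                     seed = seed),
      synthetic_spec(n_subjects = n, group_label = "B",
                     blocks = .fixture_blocks_17(0.1), r0 = 0.1,
                     seed = seedB))
  } else if (name == "paired_8") {
    n <- if (is.null(n_per_group)) 8 else n_per_group
    base <- synthetic_spec(blocks = .fixture_blocks_17(0.7), r0 = 0.1)
    eff <- c(0, -0.35, 0, 0)   # follow-up loss in the limbic block only
    make_paired_cohort(n_pairs = n, effect = eff,
                       rho_within_subject = 0.8, seed = seed, spec = base)
  } else {
    n <- if (is.null(n_per_group)) 23 else n_per_group
    base <- synthetic_spec(blocks = .fixture_blocks_17(0.7), r0 = 0.1)
    eff <- c(-0.45, -0.5, -0.45, -0.45)  # broad follow-up covariance loss
    make_paired_cohort(n_pairs = n, effect = eff,
                       rho_within_subject = 0.5, seed = seed, spec = base)
  }
}

#' Write a cohort in the stats-table + covariate-table format
#'
#' Produces the same TSV layout the readers consume (round-trip guarantee):
#' a stats table with subject id, ROI columns and an `eTIV` column, and a
#' covariate table with `subject_id`, `group`, `age`, `icv` (and `pair_id`
#' when present).
#'
#' @param cohort A `cohort`.
#' @param stats_path,covariates_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_tables <- function(cohort, stats_path, covariates_path) {
  stopifnot(inherits(cohort, "cohort"))
  tb <- structure(list(subject_ids = cohort$subjects$subject_id,
                       values = cohort$values,
                       measure_kind = cohort$measure_kind,
                       covariate_candidates =
                         data.frame(eTIV = cohort$subjects$icv)),
                  class = "roi_table")
  write_stats_table(tb, stats_path)
  cov <- cohort$subjects
  utils::write.table(cov, covariates_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(stats_path, covariates_path))
}
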