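# Permutation inference for group differences in AUC-summarized network
# properties. The full pipeline (covariance -> threshold -> metrics -> AUC)
# is recomputed for every permutation replicate; residualization is pooled
# over the two groups by default, in which case the shuffle leaves the OLS
# design unchanged and the residuals are computed once (identical results,
# see the methods vignette).

# Fast path: AUCs of the requested properties for one subject subset.
# `resid_vals` is the pooled residual matrix; `rows` selects a pseudo-group.
# The heavy lifting (correlation, deterministic nested thresholding,
# metrics, rewired nulls, trapezoidal AUC with the NaN-suffix rule) happens
# in one compiled call.
.pipeline_auc <- function(resid_vals, rows, grid, n_null_inner,
                          n_swap_per_edge, want_global, want_nodal) {
  s_values <- as.numeric(grid)
  p <- ncol(resid_vals)
  ecounts <- as.integer(floor(s_values * p * (p - 1) / 2 + 0.5))
  need_null <- any(c("gamma", "lambda", "sigma") %in% want_global)
  out <- cpp_pipeline_auc(resid_vals[rows, , drop = FALSE], s_values,
                          ecounts, as.integer(n_null_inner),
                          as.integer(n_swap_per_edge), need_null,
                          length(want_nodal) > 0L)
  n_auc <- NULL
  if (length(want_nodal) > 0L) {
    nodal <- out$nodal
    dimnames(nodal) <- list(.nodal_properties, colnames(resid_vals))
    n_auc <- nodal[want_nodal, , drop = FALSE]
  }
  list(global = out$global[want_global], nodal = n_auc)
}

.split_properties <- function(properties) {
  bad <- setdiff(properties, c(.global_properties, .nodal_properties))
  if (length(bad) > 0L) {
    stop("unknown propert(ies): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  list(global = intersect(.global_properties, properties),
       nodal = intersect(.nodal_properties, properties))
}

# Shared permutation machinery: evaluates observed and permuted AUC
# differences for an index-partition generator, assembles p-values and FDR.
.perm_infer <- function(resid_vals, node_names, idxA0, idxB0, partitions,
                        exhaustive, grid, n_null_inner, n_swap_per_edge,
                        props, seed, n_jobs, design) {
  n_perm <- length(partitions)
  # Pre-drawn seeds make results independent of scheduling/worker count.
  set.seed(seed)
  eval_seeds <- sample.int(.Machine$integer.max - 1L, n_perm + 1L)

  eval_one <- function(idxA, idxB, s) {
    set.seed(s)
    a <- .pipeline_auc(resid_vals, idxA, grid, n_null_inner,
                       n_swap_per_edge, props$global, props$nodal)
    b <- .pipeline_auc(resid_vals, idxB, grid, n_null_inner,
                       n_swap_per_edge, props$global, props$nodal)
    list(global = a$global - b$global,
         nodal = if (!is.null(a$nodal)) a$nodal - b$nodal else NULL)
  }

  observed <- eval_one(idxA0, idxB0, eval_seeds[1L])
  worker <- function(i) {
    p <- partitions[[i]]
    eval_one(p$A, p$B, eval_seeds[i + 1L])
  }
  nulls <- if (n_jobs > 1L) {
    parallel::mclapply(seq_len(n_perm), worker, mc.cores = n_jobs,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_perm), worker)
  }

  null_global <- do.call(rbind, lapply(nulls, `[[`, "global"))
  p_of <- function(obs, null_vec) {
    ok <- is.finite(null_vec)
    if (!is.finite(obs) || !any(ok)) return(NA_real_)
    if (exhaustive) mean(abs(null_vec[ok]) >= abs(obs))
    else (sum(abs(null_vec[ok]) >= abs(obs)) + 1) / (sum(ok) + 1)
  }

  rows <- list()
  for (j in seq_along(props$global)) {
    p <- props$global[j]
    rows[[length(rows) + 1L]] <- data.frame(
      design = design, property = p, node = "global",
      observed_diff = observed$global[[j]],
      p_raw = p_of(observed$global[[j]], null_global[, j]),
      p_fdr = NA_real_, stringsAsFactors = FALSE)
  }
  null_nodal <- list()
  for (p in props$nodal) {
    obs_vec <- observed$nodal[p, ]
    nm <- do.call(rbind, lapply(nulls, function(x) x$nodal[p, ]))
    null_nodal[[p]] <- nm
    p_raw <- vapply(seq_along(obs_vec), function(i)
      p_of(obs_vec[i], nm[, i]), numeric(1))
    adj <- fdr_bh(p_raw)$p_adjusted
    rows[[length(rows) + 1L]] <- data.frame(
      design = design, property = p, node = node_names,
      observed_diff = unname(obs_vec), p_raw = p_raw, p_fdr = adj,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(list(results = res,
                 null_global = null_global,
                 null_nodal = null_nodal,
                 n_perm = n_perm, exhaustive = exhaustive,
                 seed = seed, design = design,
                 properties = c(props$global, props$nodal)),
            class = "scn_perm_result")
}

#' @export
print.scn_perm_result <- function(x, ...) {
  cat("<scn_perm_result> ", x$design, " design, ", x$n_perm,
      if (x$exhaustive) " exhaustive" else " Monte Carlo",
      " permutations (seed ", x$seed, ")\n", sep = "")
  sig <- x$results[!is.na(x$results$p_raw) & x$results$p_raw < 0.05, ]
  cat("  ", nrow(sig), " of ", nrow(x$results),
      " tests with raw p < 0.05\n", sep = "")
  invisible(x)
}

#' Unpaired subject-shuffle permutation test for SCN differences
#'
#' Tests group differences in AUC-summarized network properties by shuffling
#' subjects between the two groups (preserving group sizes) and recomputing
#' the whole pipeline — residualization, positive-rectified covariance,
#' sparsity thresholding, metrics, AUC — for every relabeling. Two-tailed
#' p-values use the add-one estimator p = (b + 1) / (n_perm + 1); when the
#' number of distinct relabelings choose(nA+nB, nA) does not exceed
#' `n_perm`, all of them are enumerated and the p-value is exact.
#' Benjamini-Hochberg FDR is applied per nodal property across nodes.
#'
#' @param cohortA,cohortB Two `cohort`s with disjoint subject sets on the
#'   same atlas.
#' @param grid A [sparsity_grid()].
#' @param n_perm Number of permutations (default 5000).
#' @param n_null_inner Rewired nulls per sparsity inside each permutation
#'   replicate (default 100; the reported group curves use 1000, but the
#'   permutation engine trades null count for replicate count).
#' @param properties Which properties to test (subset of Cp, Lp, Eglob,
#'   gamma, lambda, sigma, degree, betweenness, nodal_efficiency,
#'   local_efficiency).
#' @param covariate_names Covariates removed before covariance construction.
#' @param fit_scope `"pooled"` (default) or `"per-group"` residualization.
#' @param seed Integer seed (mandatory: permutation inference is Monte
#'   Carlo).
#' @param n_swap_per_edge Rewiring intensity for inner nulls.
#' @param n_jobs Parallel workers (results are independent of this).
#' @return An `scn_perm_result`; `$results` is a data.frame with columns
#'   design, property, node, observed_diff (AUC A minus AUC B), p_raw,
#'   p_fdr.
#' @export
permutation_test_unpaired <- function(cohortA, cohortB,
                                      grid = sparsity_grid(),
                                      n_perm = 5000, n_null_inner = 100,
                                      properties = c(.global_properties,
                                                     .nodal_properties),
                                      covariate_names = c("age", "icv"),
                                      fit_scope = "pooled",
                                      seed, n_swap_per_edge = 10,
                                      n_jobs = 1) {
  stopifnot(inherits(cohortA, "cohort"), inherits(cohortB, "cohort"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (cohortA$atlas$name != cohortB$atlas$name) {
    stop("cohorts use different atlases", call. = FALSE)
  }
  overlap <- intersect(cohortA$subjects$subject_id,
                       cohortB$subjects$subject_id)
  if (length(overlap) > 0L) {
    stop("subject sets overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  nA <- nrow(cohortA$values); nB <- nrow(cohortB$values)
  if (nA < 2L || nB < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (nA < 4L || nB < 4L) {
    warning("groups with fewer than 4 subjects give degenerate Pearson ",
            "edges; interpret with care", call. = FALSE)
  }
  if (n_perm < 100) {
    warning("n_perm < 100 gives a coarse permutation p-value", call. = FALSE)
  }
  props <- .split_properties(properties)
  if (fit_scope != "pooled") {
    stop("only pooled residualization is supported in the permutation test;",
         " per-group fits would have to be recomputed per relabeling",
         call. = FALSE)
  }

  subjects <- rbind(cohortA$subjects[, c("subject_id", "group", "age", "icv")],
                    cohortB$subjects[, c("subject_id", "group", "age", "icv")])
  combined <- structure(list(subjects = subjects,
                             values = rbind(cohortA$values, cohortB$values),
                             measure_kind = cohortA$measure_kind,
                             atlas = cohortA$atlas),
                        class = "cohort")
  resid <- residualize(combined, covariate_names, fit_scope = "pooled")
  n <- nA + nB
  idxA0 <- seq_len(nA)
  idxB0 <- nA + seq_len(nB)

  n_comb <- choose(n, nA)
  exhaustive <- is.finite(n_comb) && n_comb <= n_perm
  if (exhaustive) {
    cmb <- utils::combn(n, nA)
    partitions <- lapply(seq_len(ncol(cmb)), function(i) {
      A <- cmb[, i]
      list(A = A, B = setdiff(seq_len(n), A))
    })
  } else {
    set.seed(seed)
    partitions <- lapply(seq_len(n_perm), function(i) {
      A <- sample.int(n, nA)
      list(A = A, B = setdiff(seq_len(n), A))
    })
  }
  .perm_infer(resid$residuals, colnames(resid$residuals), idxA0, idxB0,
              partitions, exhaustive, grid, n_null_inner, n_swap_per_edge,
              props, seed, n_jobs, design = "unpaired")
}

#' Paired within-pair permutation test (longitudinal design)
#'
#' For a cohort of complete pairs (e.g. baseline and follow-up scans of the
#' same patients), the permutation null is generated by independently
#' swapping the two members within each pair. All 2^K sign patterns are
#' enumerated when 2^K does not exceed `n_perm` (exact p-values); otherwise
#' patterns are sampled.
#'
#' @param paired_cohort A `cohort` whose `subjects` carry `pair_id` and a
#'   two-level `group` (e.g. scan1/scan2), one member per level per pair.
#' @inheritParams permutation_test_unpaired
#' @return An `scn_perm_result`; observed differences are AUC(first group
#'   level) minus AUC(second).
#' @export
permutation_test_paired <- function(paired_cohort, grid = sparsity_grid(),
                                    n_perm = 5000, n_null_inner = 100,
                                    properties = c(.global_properties,
                                                   .nodal_properties),
                                    covariate_names = c("age", "icv"),
                                    seed, n_swap_per_edge = 10, n_jobs = 1) {
  stopifnot(inherits(paired_cohort, "cohort"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  subj <- paired_cohort$subjects
  if (is.null(subj$pair_id)) {
    stop("paired design requires a pair_id column", call. = FALSE)
  }
  lev <- unique(subj$group)
  if (length(lev) != 2L) {
    stop("paired design requires exactly 2 group levels, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  split_pairs <- split(seq_len(nrow(subj)), subj$pair_id)
  bad <- names(split_pairs)[vapply(split_pairs, function(ix)
    length(ix) != 2L || !setequal(subj$group[ix], lev), logical(1))]
  if (length(bad) > 0L) {
    stop("incomplete or malformed pair(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  props <- .split_properties(properties)
  K <- length(split_pairs)
  first <- vapply(split_pairs, function(ix)
    ix[subj$group[ix] == lev[1L]], integer(1))
  second <- vapply(split_pairs, function(ix)
    ix[subj$group[ix] == lev[2L]], integer(1))

  resid <- residualize(paired_cohort, covariate_names, fit_scope = "pooled")

  exhaustive <- K <= 25 && 2^K <= n_perm
  make_partition <- function(w) {   # w: logical swap flags per pair
    A <- ifelse(w, second, first)
    B <- ifelse(w, first, second)
    list(A = A, B = B)
  }
  if (exhaustive) {
    n_pat <- 2^K
    partitions <- lapply(seq_len(n_pat) - 1L, function(code)
      make_partition(bitwAnd(code, bitwShiftL(1L, seq_len(K) - 1L)) > 0L))
  } else {
    set.seed(seed)
    partitions <- lapply(seq_len(n_perm), function(i)
      make_partition(stats::runif(K) < 0.5))
  }
  .perm_infer(resid$residuals, colnames(resid$residuals),
              unname(first), unname(second), partitions, exhaustive, grid,
              n_null_inner, n_swap_per_edge, props, seed, n_jobs,
              design = "paired")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values and rejection flags at level `q`.
#'
#' @param p_values Raw p-values in \[0, 1\] (NA allowed, propagated).
#' @param q FDR level (default 0.05).
#' @return List: `p_adjusted`, `rejected` (logical).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) {
    return(list(p_adjusted = numeric(0), rejected = logical(0)))
  }
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Significance backbone of a covariance matrix
#'
#' Retains an edge when its positive Pearson correlation is significant by
#' the one-sample correlation t-test, t = r * sqrt((n - 2) / (1 - r^2)),
#' two-tailed p < `alpha`. Used for the "group average nodal connections"
#' shown alongside nodal comparisons. Perfect correlations (r = 1) are
#' retained (p = 0); rectified (non-positive) correlations never are.
#'
#' @param cov An `scn_cov`.
#' @param alpha Uncorrected significance level (default 0.001).
#' @return Logical symmetric matrix mask, FALSE diagonal.
#' @export
edge_backbone <- function(cov, alpha = 0.001) {
  stopifnot(inherits(cov, "scn_cov"))
  n <- cov$n_subjects
  if (n < 4L) stop("need n_subjects >= 4", call. = FALSE)
  r <- cov$r
  p <- matrix(1, nrow(r), ncol(r), dimnames = dimnames(r))
  pos <- r > 0 & r < 1
  tstat <- r[pos] * sqrt((n - 2) / (1 - r[pos]^2))
  p[pos] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[r >= 1] <- 0
  mask <- p < alpha
  diag(mask) <- FALSE
  mask
}
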