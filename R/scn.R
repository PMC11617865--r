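# Construction of group structural covariance networks: positive-rectified
# Pearson correlation matrices, sparsity thresholding, and the sparsity grid.

#' Sparsity grid for network thresholding
#'
#' The sparsity value s is the fraction of the N(N-1)/2 possible edges kept
#' when binarizing a covariance matrix. The default grid, 0.05 to 0.40 in
#' steps of 0.01 (36 values), spans the range over which group covariance
#' networks retain small-world organisation while staying connected enough
#' for stable metrics.
#'
#' @param start,stop,step Grid limits and increment.
#' @return Object of class `sparsity_grid` (numeric vector of grid values
#'   with attributes).
#' @export
sparsity_grid <- function(start = 0.05, stop = 0.40, step = 0.01) {
  if (!(start > 0 && start <= stop && stop < 1 && step > 0)) {
    stop("invalid sparsity grid: need 0 < start <= stop < 1, step > 0",
         call. = FALSE)
  }
  values <- seq(start, stop, by = step)
  # guard against seq() dropping the endpoint to fp error
  if (abs(values[length(values)] - stop) > step / 2) values <- c(values, stop)
  values <- round(values, 10)
  structure(values, start = start, stop = stop, step = step,
            class = c("sparsity_grid", "numeric"))
}

#' Group covariance (structural covariance) matrix
#'
#' Pearson correlations between all ROI pairs across the subjects of one
#' group, computed on residualized values. Negative correlations are
#' rectified to zero (only positive covariance enters the network) and the
#' diagonal is zero.
#'
#' @param residuals A `residual_matrix` from [residualize()].
#' @param group Group label selecting the subjects; `NULL` uses all rows
#'   (e.g. when `residuals` already holds a single group).
#' @return Object of class `scn_cov`: `r` (N x N rectified correlation
#'   matrix), `r_raw` (unrectified, for edge-backbone tests), `n_subjects`,
#'   `group`, `atlas`.
#' @export
covariance_matrix <- function(residuals, group = NULL) {
  stopifnot(inherits(residuals, "residual_matrix"))
  if (is.null(group)) {
    rows <- seq_len(nrow(residuals$residuals))
  } else {
    rows <- which(residuals$group_labels == group)
    if (length(rows) == 0L) {
      stop("no subjects with group label '", group, "'", call. = FALSE)
    }
  }
  if (length(rows) < 4L) {
    stop("need at least 4 subjects for a covariance network; group '",
         group, "' has ", length(rows), call. = FALSE)
  }
  X <- residuals$residuals[rows, , drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  # residualized constants come back as ~1e-16 noise: flag relatively
  sds[sds < max(sds) * 1e-10] <- 0
  if (any(sds == 0)) {
    stop("zero-variance ROI column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r_raw <- stats::cor(X)
  r <- pmax(r_raw, 0)
  diag(r) <- 0
  diag(r_raw) <- 0
  structure(list(r = r, r_raw = r_raw, n_subjects = length(rows),
                 group = if (is.null(group)) NA_character_ else group,
                 atlas = residuals$atlas),
            class = "scn_cov")
}

#' @export
print.scn_cov <- function(x, ...) {
  cat("<scn_cov> ", nrow(x$r), "x", ncol(x$r), " positive-rectified Pearson",
      " matrix; group ", x$group, ", n = ", x$n_subjects, "\n", sep = "")
  invisible(x)
}

# Deterministic ordering of upper-triangle entries: descending correlation,
# ties broken by ascending (i, j). Correlations are rounded to 12 decimals
# first so that values equal up to floating-point noise (e.g. the exact +/-1
# correlations of two-subject groups) fall under the tie rule instead of
# being ordered by that noise. This fixed rule makes thresholding
# reproducible and edge sets nested across the sparsity grid.
.edge_order <- function(r) {
  ij <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[upper.tri(r)]
  ord <- order(-round(vals, 12L), ij[, 1L], ij[, 2L])
  list(ij = ij[ord, , drop = FALSE], vals = vals[ord])
}

#' Threshold a covariance matrix at one sparsity value
#'
#' Keeps the E = round(s * N(N-1)/2) strongest positive correlations
#' (round-half-up; ties broken by node-index order) as the edges of a binary
#' undirected graph. If the matrix has fewer than E positive entries, all of
#' them are kept and a warning is emitted.
#'
#' @param cov An `scn_cov` or a symmetric correlation matrix.
#' @param s Sparsity in (0, 1).
#' @return Binary integer adjacency matrix (symmetric, zero diagonal).
#' @export
threshold_at_sparsity <- function(cov, s) {
  r <- if (inherits(cov, "scn_cov")) cov$r else as.matrix(cov)
  if (!(is.numeric(s) && length(s) == 1L && s > 0 && s < 1)) {
    stop("sparsity must be a single value in (0, 1)", call. = FALSE)
  }
  n <- nrow(r)
  m <- n * (n - 1) / 2
  e_target <- floor(s * m + 0.5)
  eo <- .edge_order(r)
  n_pos <- sum(eo$vals > 0)
  if (n_pos < e_target) {
    warning("only ", n_pos, " positive correlations available for ",
            e_target, " requested edges at sparsity ", s, call. = FALSE)
  }
  keep <- seq_len(min(e_target, n_pos))
  adj <- matrix(0L, n, n, dimnames = dimnames(r))
  if (length(keep) > 0L) {
    ij <- eo$ij[keep, , drop = FALSE]
    adj[ij] <- 1L
    adj[ij[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  adj
}

#' Build the full stack of thresholded graphs over a sparsity grid
#'
#' @param cov An `scn_cov`.
#' @param grid A [sparsity_grid()].
#' @return Object of class `graph_stack`: `sparsity` (grid values),
#'   `adjacency` (list of binary matrices), `edge_counts`, `atlas`, `group`.
#' @export
build_graph_stack <- function(cov, grid = sparsity_grid()) {
  stopifnot(inherits(cov, "scn_cov"))
  adjacency <- lapply(as.numeric(grid), function(s)
    threshold_at_sparsity(cov, s))
  structure(list(sparsity = as.numeric(grid),
                 adjacency = adjacency,
                 edge_counts = vapply(adjacency, function(a) sum(a) %/% 2L,
                                      integer(1)),
                 atlas = cov$atlas, group = cov$group),
            class = "graph_stack")
}

#' @export
print.graph_stack <- function(x, ...) {
  cat("<graph_stack> ", length(x$sparsity), " graphs on ",
      nrow(x$adjacency[[1L]]), " nodes; sparsity ",
      min(x$sparsity), "-", max(x$sparsity), ", edges ",
      min(x$edge_counts), "-", max(x$edge_counts), "\n", sep = "")
  invisible(x)
}

#' Fraction of the sparsity grid with small-world organisation
#'
#' Computes the small-world index sigma = gamma / lambda at every sparsity
#' value of a graph stack (against `n_null` degree-preserving rewired nulls)
#' and returns the fraction of grid values with sigma > 1.1. The sparsity
#' range is considered adequate when this fraction exceeds 0.90; a warning
#' (not an error) is emitted otherwise.
#'
#' @param stack A `graph_stack`.
#' @param n_null Number of rewired null networks per sparsity (>= 20).
#' @param seed Optional integer seed (`NULL` leaves the RNG state alone).
#' @param n_swap_per_edge Rewiring intensity.
#' @return The fraction, with attribute `"sigma"` holding the per-sparsity
#'   sigma values.
#' @export
check_small_world_range <- function(stack, n_null = 100, seed = NULL,
                                    n_swap_per_edge = 10) {
  stopifnot(inherits(stack, "graph_stack"))
  if (n_null < 20) {
    stop("n_null must be at least 20 for a stable sigma estimate",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sig <- vapply(stack$adjacency, function(adj) {
    sw <- small_world_indices(adj, n_null = n_null,
                              n_swap_per_edge = n_swap_per_edge)
    sw$sigma
  }, numeric(1))
  frac <- mean(!is.na(sig) & sig > 1.1)
  if (frac <= 0.90) {
    warning(sprintf(
      "only %.0f%% of sparsity values are small-world (sigma > 1.1); the >90%% range criterion is not met",
      100 * frac), call. = FALSE)
  }
  structure(frac, sigma = sig)
}

#' Export a covariance or adjacency matrix as TSV
#'
#' @param m An `scn_cov` or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  x <- if (inherits(m, "scn_cov")) m$r else as.matrix(m)
  df <- data.frame(roi = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
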