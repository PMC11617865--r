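# Graph-theoretic network properties of binary undirected graphs, the
# degree-preserving null model, small-world normalization, and AUC-over-
# sparsity summaries. The per-graph algorithms live in src/graph_core.cpp;
# these wrappers validate inputs and fix the conventions:
#   * disconnected graphs: Lp averages finite-distance pairs only,
#     efficiencies use 1/Inf = 0;
#   * betweenness is unnormalized (Brandes pair counts, endpoints excluded);
#   * clustering C_i = 0 when degree < 2.

.check_adj <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) || !all(adj %in% c(0, 1)) ||
      !isTRUE(all.equal(adj, t(adj))) || any(diag(adj) != 0)) {
    stop("adjacency must be a binary symmetric matrix with zero diagonal",
         call. = FALSE)
  }
  storage.mode(adj) <- "integer"
  adj
}

#' Nodal degree centrality
#' @param adj Binary symmetric adjacency matrix, zero diagonal.
#' @return Integer vector of neighbour counts.
#' @export
degree_centrality <- function(adj) {
  adj <- .check_adj(adj)
  structure(as.integer(rowSums(adj)), names = rownames(adj))
}

#' Nodal betweenness centrality (unnormalized Brandes)
#' @inheritParams degree_centrality
#' @return Numeric vector; the number of shortest paths between other node
#'   pairs passing through each node (fractional under geodesic ties).
#' @export
betweenness_centrality <- function(adj) {
  adj <- .check_adj(adj)
  structure(cpp_nodal_metrics(adj)$betweenness, names = rownames(adj))
}

#' Nodal clustering coefficients and their mean Cp
#' @inheritParams degree_centrality
#' @return List with `ci` (per-node) and `Cp` (mean over all nodes).
#' @export
clustering_coefficients <- function(adj) {
  adj <- .check_adj(adj)
  ci <- cpp_nodal_metrics(adj)$clustering
  list(ci = structure(ci, names = rownames(adj)), Cp = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs at finite distance;
#' pairs in different components are excluded. `NaN` (with a warning) when
#' the graph has no edges.
#' @inheritParams degree_centrality
#' @return Lp.
#' @export
characteristic_path_length <- function(adj) {
  adj <- .check_adj(adj)
  lp <- cpp_global_metrics(adj)$Lp
  if (is.nan(lp)) warning("graph has no edges; Lp undefined", call. = FALSE)
  lp
}

#' Global, nodal and local efficiency
#'
#' Global efficiency is the mean over ordered pairs of inverse shortest-path
#' length (1/Inf = 0); nodal efficiency of i is the mean of 1/d(i, j) over
#' j != i; local efficiency of i is the global efficiency of the subgraph
#' induced by the neighbours of i (0 when degree < 2).
#' @inheritParams degree_centrality
#' @return `global_efficiency()`: scalar. `nodal_efficiency()`,
#'   `local_efficiency()`: numeric vectors.
#' @export
global_efficiency <- function(adj) {
  adj <- .check_adj(adj)
  cpp_global_metrics(adj)$Eglob
}

#' @rdname global_efficiency
#' @export
nodal_efficiency <- function(adj) {
  adj <- .check_adj(adj)
  structure(cpp_nodal_metrics(adj)$nodal_efficiency, names = rownames(adj))
}

#' @rdname global_efficiency
#' @export
local_efficiency <- function(adj) {
  adj <- .check_adj(adj)
  structure(cpp_nodal_metrics(adj)$local_efficiency, names = rownames(adj))
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Repeatedly swaps the endpoints of random edge pairs, rejecting swaps that
#' would create self-loops or multi-edges, so the degree sequence is exactly
#' preserved while all other structure is randomized. Graphs admitting no
#' legal swap (e.g. complete graphs) are returned unchanged.
#'
#' Uses R's RNG: call `set.seed()` for reproducibility.
#'
#' @inheritParams degree_centrality
#' @param n_swap_per_edge Attempted swaps per edge (default 10).
#' @return Rewired adjacency matrix of the same degree sequence.
#' @export
rewire_degree_preserving <- function(adj, n_swap_per_edge = 10) {
  adj <- .check_adj(adj)
  if (sum(adj) < 4L) return(adj)   # fewer than 2 edges: nothing to swap
  out <- cpp_rewire(adj, as.integer(n_swap_per_edge))
  dimnames(out) <- dimnames(adj)
  out
}

#' Small-world indices against a rewired null ensemble
#'
#' gamma = Cp / mean(Cp of rewired nulls), lambda = Lp / mean(Lp of rewired
#' nulls), sigma = gamma / lambda. A graph is conventionally called
#' small-world when sigma > 1.1 (much more clustered than random at similar
#' path length). NaN propagates when a null mean is zero or undefined.
#'
#' @inheritParams rewire_degree_preserving
#' @param n_null Number of rewired null networks (>= 20).
#' @return List: `gamma`, `lambda`, `sigma`, `Cp`, `Lp`, `Cp_rand`, `Lp_rand`.
#' @export
small_world_indices <- function(adj, n_null = 1000, n_swap_per_edge = 10) {
  adj <- .check_adj(adj)
  if (n_null < 20) stop("n_null must be >= 20", call. = FALSE)
  g <- cpp_global_metrics(adj)
  nulls <- cpp_null_cp_lp(adj, as.integer(n_null),
                          as.integer(n_swap_per_edge))
  cp_rand <- mean(nulls[, 1L])
  lp_rand <- mean(nulls[, 2L])
  gamma <- if (isTRUE(cp_rand > 0)) g$Cp / cp_rand else NaN
  lambda <- if (isTRUE(lp_rand > 0)) g$Lp / lp_rand else NaN
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = g$Cp, Lp = g$Lp, Cp_rand = cp_rand, Lp_rand = lp_rand)
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of a per-sparsity property curve, the threshold-free
#' summary statistic used for group comparison. Leading `NaN` values (e.g.
#' an undefined Lp on a nearly empty low-sparsity graph) are dropped: the
#' integral is taken over the largest NaN-free suffix of the grid, with a
#' warning. An all-NaN curve is an error.
#'
#' @param values Numeric curve, one value per grid point.
#' @param grid A [sparsity_grid()] (or numeric vector of grid values).
#' @return The trapezoidal AUC.
#' @export
auc_over_grid <- function(values, grid) {
  s <- as.numeric(grid)
  stopifnot(length(values) == length(s))
  ok <- is.finite(values)
  if (!any(ok)) stop("AUC undefined: all curve values are NaN", call. = FALSE)
  if (!all(ok)) {
    first <- max(which(!ok)) + 1L
    if (first > length(s)) {
      stop("AUC undefined: curve has no NaN-free suffix", call. = FALSE)
    }
    warning("dropping ", first - 1L, " leading grid point(s) with undefined ",
            "values before AUC", call. = FALSE)
    values <- values[first:length(values)]
    s <- s[first:length(s)]
  }
  if (length(s) < 2L) {
    stop("AUC needs at least 2 finite grid points", call. = FALSE)
  }
  sum(diff(s) * (head(values, -1L) + values[-1L]) / 2)
}

.global_properties <- c("Cp", "Lp", "Eglob", "gamma", "lambda", "sigma")
.nodal_properties <- c("degree", "betweenness", "nodal_efficiency",
                       "local_efficiency")

#' All network properties across a graph stack, with AUC summaries
#'
#' Computes the global properties (Cp, Lp, Eglob, and the null-normalized
#' gamma, lambda, sigma) and nodal properties (degree, betweenness, nodal
#' and local efficiency) at every sparsity value of a stack, plus the
#' trapezoidal AUC of each curve. Null networks are regenerated per sparsity
#' value. Deterministic for a fixed RNG state.
#'
#' @param stack A `graph_stack`.
#' @param n_null Rewired nulls per sparsity for gamma/lambda/sigma.
#' @param seed Optional integer seed.
#' @param n_swap_per_edge Rewiring intensity.
#' @return Object of class `metric_curves`: `sparsity`, `global` (data.frame
#'   sparsity x property), `nodal` (list of property -> node x sparsity
#'   matrix), `auc_global` (named vector), `auc_nodal` (property x node
#'   matrix), `n_null`.
#' @export
compute_metric_curves <- function(stack, n_null = 1000, seed = NULL,
                                  n_swap_per_edge = 10) {
  stopifnot(inherits(stack, "graph_stack"))
  if (!is.null(seed)) set.seed(seed)
  ns <- length(stack$sparsity)
  n_nodes <- nrow(stack$adjacency[[1L]])
  node_names <- rownames(stack$adjacency[[1L]])
  if (is.null(node_names)) node_names <- paste0("node", seq_len(n_nodes))

  glob <- matrix(NA_real_, ns, length(.global_properties) + 2L,
                 dimnames = list(NULL, c(.global_properties,
                                         "Cp_rand", "Lp_rand")))
  nodal <- lapply(.nodal_properties, function(p)
    matrix(NA_real_, n_nodes, ns, dimnames = list(node_names, NULL)))
  names(nodal) <- .nodal_properties

  for (k in seq_len(ns)) {
    adj <- stack$adjacency[[k]]
    sw <- suppressWarnings(
      small_world_indices(adj, n_null = n_null,
                          n_swap_per_edge = n_swap_per_edge))
    glob[k, ] <- c(sw$Cp, sw$Lp, cpp_global_metrics(adj)$Eglob,
                   sw$gamma, sw$lambda, sw$sigma, sw$Cp_rand, sw$Lp_rand)
    nm <- cpp_nodal_metrics(adj)
    nodal$degree[, k] <- nm$degree
    nodal$betweenness[, k] <- nm$betweenness
    nodal$nodal_efficiency[, k] <- nm$nodal_efficiency
    nodal$local_efficiency[, k] <- nm$local_efficiency
  }

  auc_global <- vapply(.global_properties, function(p)
    suppressWarnings(auc_over_grid(glob[, p], stack$sparsity)), numeric(1))
  auc_nodal <- t(vapply(.nodal_properties, function(p)
    vapply(seq_len(n_nodes), function(i)
      suppressWarnings(auc_over_grid(nodal[[p]][i, ], stack$sparsity)),
      numeric(1)),
    numeric(n_nodes)))
  colnames(auc_nodal) <- node_names

  structure(list(sparsity = stack$sparsity,
                 global = as.data.frame(cbind(sparsity = stack$sparsity,
                                              glob)),
                 nodal = nodal,
                 auc_global = auc_global,
                 auc_nodal = auc_nodal,
                 n_null = n_null,
                 group = stack$group),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat("<metric_curves> ", length(x$sparsity), " sparsity values, ",
      nrow(x$nodal$degree), " nodes; global AUCs:\n", sep = "")
  print(round(x$auc_global, 4))
  invisible(x)
}

#' Export metric curves as long-format TSV rows
#'
#' @param curves A `metric_curves`.
#' @param group Group label recorded in the output.
#' @return data.frame with columns group, property, node, sparsity, value.
#' @export
curves_long <- function(curves, group = curves$group) {
  stopifnot(inherits(curves, "metric_curves"))
  s <- curves$sparsity
  glob <- do.call(rbind, lapply(.global_properties, function(p)
    data.frame(group = group, property = p, node = "global", sparsity = s,
               value = curves$global[[p]], stringsAsFactors = FALSE)))
  nod <- do.call(rbind, lapply(.nodal_properties, function(p) {
    m <- curves$nodal[[p]]
    data.frame(group = group, property = p,
               node = rep(rownames(m), times = length(s)),
               sparsity = rep(s, each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  rbind(glob, nod)
}
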