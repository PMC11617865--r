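# Brute-force oracles, independent of the package's compiled algorithms.
# All operate on binary symmetric adjacency matrices with zero diagonal.

# Floyd-Warshall all-pairs shortest paths.
o_distances <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

o_degree <- function(adj) rowSums(adj)

o_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  })
}

o_lp <- function(adj) {
  D <- o_distances(adj)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (length(d) == 0) return(NaN)
  mean(d)
}

o_eglob <- function(adj) {
  D <- o_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

o_nodal_eff <- function(adj) {
  D <- o_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

o_local_eff <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    o_eglob(adj[nb, nb, drop = FALSE])
  })
}

# Exhaustive geodesic enumeration: betweenness by listing every shortest
# path between every pair (endpoints excluded, fractional under ties).
o_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- o_distances(adj)
  bc <- numeric(n)
  geodesics <- function(s, t) {
    out <- list()
    expand <- function(path) {
      u <- path[length(path)]
      if (u == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
      for (v in which(adj[u, ] == 1)) {
        if (D[s, v] == D[s, u] + 1 && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) expand(c(path, v))
      }
    }
    expand(s)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] < 2) next
    ps <- geodesics(s, t)
    w <- 1 / length(ps)
    for (p in ps) {
      inner <- p[-c(1L, length(p))]
      bc[inner] <- bc[inner] + w
    }
  }
  bc
}

# Random Erdos-Renyi-ish adjacency with given edge probability.
rand_adj <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Ring lattice: each node connected to k nearest neighbours (k even).
ring_lattice <- function(n, k) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}

# Build a cohort object directly from a value matrix (bypasses file IO).
make_cohort <- function(values, group = "G", age = NULL, icv = NULL,
                        atlas = NULL, pair_id = NULL) {
  n <- nrow(values)
  if (is.null(age)) age <- rep(60, n)
  if (is.null(icv)) icv <- rep(1.4e6, n)
  if (is.null(atlas)) {
    atlas <- structure(list(name = "custom",
                            roi_names = colnames(values),
                            hemisphere = rep("bilateral", ncol(values)),
                            n_nodes = ncol(values)),
                       class = "atlas_spec")
  }
  ids <- if (is.null(rownames(values)))
    sprintf("s%03d", seq_len(n)) else rownames(values)
  rownames(values) <- ids
  subjects <- data.frame(subject_id = ids,
                         group = rep_len(group, n),
                         age = age, icv = icv, stringsAsFactors = FALSE)
  if (!is.null(pair_id)) subjects$pair_id <- pair_id
  structure(list(subjects = subjects, values = values,
                 measure_kind = "volume", atlas = atlas),
            class = "cohort")
}

# Concatenate two cohorts on the same atlas.
bind_cohorts <- function(a, b) {
  structure(list(subjects = rbind(a$subjects, b$subjects),
                 values = rbind(a$values, b$values),
                 measure_kind = a$measure_kind, atlas = a$atlas),
            class = "cohort")
}
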