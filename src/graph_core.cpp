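#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>
#include <cmath>
using namespace Rcpp;

// Binary undirected graphs are passed as 0/1 integer adjacency matrices with
// zero diagonal. Validation happens on the R side; these routines assume a
// well-formed input and are the hot path of the permutation engine.

typedef std::vector< std::vector<int> > AdjList;

static AdjList to_adjlist(const IntegerMatrix& A) {
  int n = A.nrow();
  AdjList nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0 && i != j) nb[i].push_back(j);
  return nb;
}

// BFS distances from source s; -1 marks unreachable.
static void bfs(const AdjList& nb, int s, std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[s] = 0;
  std::queue<int> q;
  q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (size_t k = 0; k < nb[u].size(); ++k) {
      int v = nb[u][k];
      if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_distances(IntegerMatrix A) {
  int n = A.nrow();
  AdjList nb = to_adjlist(A);
  NumericMatrix D(n, n);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    bfs(nb, s, dist);
    for (int j = 0; j < n; ++j)
      D(s, j) = dist[j] < 0 ? R_PosInf : (double)dist[j];
  }
  return D;
}

// Per-node clustering coefficients: fraction of neighbour pairs connected.
static void clustering(const IntegerMatrix& A, const AdjList& nb,
                       std::vector<double>& C) {
  int n = A.nrow();
  for (int i = 0; i < n; ++i) {
    int k = nb[i].size();
    if (k < 2) { C[i] = 0.0; continue; }
    int links = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (A(nb[i][a], nb[i][b])) ++links;
    C[i] = 2.0 * links / ((double)k * (k - 1));
  }
}

struct GlobalStats { double Cp, Lp, Eglob; };

static GlobalStats global_stats(const IntegerMatrix& A, const AdjList& nb) {
  int n = A.nrow();
  std::vector<double> C(n);
  clustering(A, nb, C);
  double cp = 0.0;
  for (int i = 0; i < n; ++i) cp += C[i];
  cp /= n;

  std::vector<int> dist(n);
  double lsum = 0.0, esum = 0.0;
  long   lcnt = 0;
  for (int s = 0; s < n; ++s) {
    bfs(nb, s, dist);
    for (int j = 0; j < n; ++j) {
      if (j == s) continue;
      if (dist[j] > 0) { lsum += dist[j]; ++lcnt; esum += 1.0 / dist[j]; }
    }
  }
  GlobalStats g;
  g.Cp = cp;
  g.Lp = lcnt > 0 ? lsum / lcnt : R_NaN;       // finite-pairs convention
  g.Eglob = n > 1 ? esum / ((double)n * (n - 1)) : R_NaN;
  return g;
}

// [[Rcpp::export]]
List cpp_global_metrics(IntegerMatrix A) {
  AdjList nb = to_adjlist(A);
  GlobalStats g = global_stats(A, nb);
  return List::create(_["Cp"] = g.Cp, _["Lp"] = g.Lp, _["Eglob"] = g.Eglob);
}

// Brandes betweenness for unweighted undirected graphs; unnormalized,
// endpoints excluded, each unordered pair counted once.
static void brandes(const AdjList& nb, std::vector<double>& bc) {
  int n = nb.size();
  std::fill(bc.begin(), bc.end(), 0.0);
  std::vector<int> dist(n), sigma(n);
  std::vector<double> delta(n);
  std::vector< std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    std::stack<int> S;
    std::queue<int> Q;
    dist[s] = 0; sigma[s] = 1; Q.push(s);
    while (!Q.empty()) {
      int u = Q.front(); Q.pop();
      S.push(u);
      for (size_t k = 0; k < nb[u].size(); ++k) {
        int v = nb[u][k];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; Q.push(v); }
        if (dist[v] == dist[u] + 1) { sigma[v] += sigma[u]; pred[v].push_back(u); }
      }
    }
    while (!S.empty()) {
      int w = S.top(); S.pop();
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int u = pred[w][k];
        delta[u] += ((double)sigma[u] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;   // undirected pairs counted once
}

// Global efficiency of the subgraph induced by the neighbours of node i.
static double local_eff_node(const IntegerMatrix& A, const std::vector<int>& nbi) {
  int k = nbi.size();
  if (k < 2) return 0.0;
  AdjList sub(k);
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b)
      if (a != b && A(nbi[a], nbi[b])) sub[a].push_back(b);
  std::vector<int> dist(k);
  double esum = 0.0;
  for (int s = 0; s < k; ++s) {
    bfs(sub, s, dist);
    for (int j = 0; j < k; ++j)
      if (j != s && dist[j] > 0) esum += 1.0 / dist[j];
  }
  return esum / ((double)k * (k - 1));
}

// [[Rcpp::export]]
List cpp_nodal_metrics(IntegerMatrix A) {
  int n = A.nrow();
  AdjList nb = to_adjlist(A);
  NumericVector deg(n), btw(n), neff(n), leff(n), clus(n);
  std::vector<double> bc(n), C(n);
  brandes(nb, bc);
  clustering(A, nb, C);
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    deg[i] = (double)nb[i].size();
    btw[i] = bc[i];
    clus[i] = C[i];
    bfs(nb, i, dist);
    double esum = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) esum += 1.0 / dist[j];
    neff[i] = n > 1 ? esum / (n - 1) : R_NaN;
    leff[i] = local_eff_node(A, nb[i]);
  }
  return List::create(_["degree"] = deg, _["betweenness"] = btw,
                      _["nodal_efficiency"] = neff,
                      _["local_efficiency"] = leff,
                      _["clustering"] = clus);
}

// Maslov-Sneppen degree-preserving rewiring. Edge list representation;
// attempts = n_swap_per_edge * E. Uses R's RNG so set.seed() governs it.
static void rewire_in_place(IntegerMatrix& A, int n_swap_per_edge) {
  int n = A.nrow();
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j)) { ei.push_back(i); ej.push_back(j); }
  int E = ei.size();
  if (E < 2) return;
  long attempts = (long)n_swap_per_edge * E;
  for (long t = 0; t < attempts; ++t) {
    int e1 = (int)(unif_rand() * E);
    int e2 = (int)(unif_rand() * E);
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposed swap: (a,b),(c,d) -> (a,d),(c,b)
    if (a == c || a == d || b == c || b == d) continue;
    if (A(a, d) || A(c, b)) continue;
    A(a, b) = A(b, a) = 0;
    A(c, d) = A(d, c) = 0;
    A(a, d) = A(d, a) = 1;
    A(c, b) = A(b, c) = 1;
    ei[e1] = a; ej[e1] = d;
    ei[e2] = c; ej[e2] = b;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerMatrix A, int n_swap_per_edge) {
  IntegerMatrix B = clone(A);
  rewire_in_place(B, n_swap_per_edge);
  return B;
}

// Allocation-free null ensemble: Cp and Lp means over n_null rewired
// copies of A, using flat reusable buffers (this sits inside the
// permutation engine's innermost loop).
static void null_ensemble_cp_lp(const IntegerMatrix& A, int n_null,
                                int n_swap_per_edge,
                                double& cp_rand, double& lp_rand) {
  int p = A.nrow();
  std::vector<int> base_adj(p * p), adj(p * p);
  std::vector<int> bei, bej;
  for (int i = 0; i < p; ++i) for (int j = 0; j < p; ++j)
    base_adj[i * p + j] = A(i, j);
  for (int i = 0; i < p; ++i) for (int j = i + 1; j < p; ++j)
    if (base_adj[i * p + j]) { bei.push_back(i); bej.push_back(j); }
  int E = bei.size();
  std::vector<int> ei(E), ej(E);
  std::vector<int> head(p + 1), nbr(2 * E), deg(p), dist(p), q(p);
  double cp_sum = 0, lp_sum = 0;
  int lp_n = 0;
  long attempts = (long)n_swap_per_edge * E;
  for (int rep = 0; rep < n_null; ++rep) {
    std::copy(base_adj.begin(), base_adj.end(), adj.begin());
    std::copy(bei.begin(), bei.end(), ei.begin());
    std::copy(bej.begin(), bej.end(), ej.begin());
    if (E >= 2) {
      for (long t = 0; t < attempts; ++t) {
        int e1 = (int)(unif_rand() * E), e2 = (int)(unif_rand() * E);
        if (e1 == e2) continue;
        int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
        if (unif_rand() < 0.5) std::swap(c, d);
        if (a == c || a == d || b == c || b == d) continue;
        if (adj[a * p + d] || adj[c * p + b]) continue;
        adj[a * p + b] = adj[b * p + a] = 0;
        adj[c * p + d] = adj[d * p + c] = 0;
        adj[a * p + d] = adj[d * p + a] = 1;
        adj[c * p + b] = adj[b * p + c] = 1;
        ei[e1] = a; ej[e1] = d; ei[e2] = c; ej[e2] = b;
      }
    }
    // flat adjacency list
    std::fill(deg.begin(), deg.end(), 0);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) if (adj[i * p + j]) ++deg[i];
    head[0] = 0;
    for (int i = 0; i < p; ++i) head[i + 1] = head[i] + deg[i];
    {
      std::vector<int> pos(head.begin(), head.end() - 1);
      for (int i = 0; i < p; ++i)
        for (int j = 0; j < p; ++j)
          if (adj[i * p + j]) nbr[pos[i]++] = j;
    }
    // clustering
    double cp = 0;
    for (int i = 0; i < p; ++i) {
      int k = deg[i];
      if (k < 2) continue;
      int links = 0;
      for (int a = head[i]; a < head[i + 1]; ++a)
        for (int b = a + 1; b < head[i + 1]; ++b)
          if (adj[nbr[a] * p + nbr[b]]) ++links;
      cp += 2.0 * links / ((double)k * (k - 1));
    }
    cp_sum += cp / p;
    // Lp over finite pairs via BFS
    double lsum = 0; long lcnt = 0;
    for (int s = 0; s < p; ++s) {
      std::fill(dist.begin(), dist.end(), -1);
      int qh = 0, qt = 0;
      dist[s] = 0; q[qt++] = s;
      while (qh < qt) {
        int u = q[qh++];
        for (int a = head[u]; a < head[u + 1]; ++a) {
          int v = nbr[a];
          if (dist[v] < 0) { dist[v] = dist[u] + 1; q[qt++] = v; }
        }
      }
      for (int j = 0; j < p; ++j)
        if (j != s && dist[j] > 0) { lsum += dist[j]; ++lcnt; }
    }
    if (lcnt > 0) { lp_sum += lsum / lcnt; ++lp_n; }
  }
  cp_rand = n_null > 0 ? cp_sum / n_null : R_NaN;
  lp_rand = lp_n == n_null && n_null > 0 ? lp_sum / n_null : R_NaN;
}

// Trapezoidal AUC over the largest suffix of finite values; NaN when fewer
// than two finite points remain (mirrors the R-level convention).
static double auc_suffix(const std::vector<double>& y,
                         const NumericVector& s) {
  int ns = y.size();
  int start = 0;
  for (int k = 0; k < ns; ++k) if (!R_finite(y[k])) start = k + 1;
  if (ns - start < 2) return R_NaN;
  double a = 0.0;
  for (int k = start + 1; k < ns; ++k)
    a += (s[k] - s[k - 1]) * (y[k] + y[k - 1]) / 2.0;
  return a;
}

// One full pipeline evaluation for a subject subset: Pearson correlation of
// the columns of X, positive rectification, deterministic edge ordering
// (descending correlation rounded to 12 decimals, ties by ascending (i,j)),
// nested thresholding at the requested per-sparsity edge counts, global
// metrics (plus rewired-null gamma/lambda/sigma) and optionally nodal
// metrics, each summarized as AUC over the sparsity grid. This is the hot
// path of the permutation engine.
// [[Rcpp::export]]
List cpp_pipeline_auc(NumericMatrix X, NumericVector svals,
                      IntegerVector ecounts, int n_null,
                      int n_swap_per_edge, bool need_null,
                      bool need_nodal) {
  int n = X.nrow(), p = X.ncol();
  // column-standardized Pearson correlations
  std::vector<double> mean(p), sd(p);
  for (int j = 0; j < p; ++j) {
    double m = 0; for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    double v = 0; for (int i = 0; i < n; ++i) v += (X(i, j) - m) * (X(i, j) - m);
    mean[j] = m; sd[j] = std::sqrt(v);
  }
  struct Edge { double key; int i, j; };
  std::vector<Edge> edges;
  edges.reserve(p * (p - 1) / 2);
  for (int i = 0; i < p; ++i) for (int j = i + 1; j < p; ++j) {
    double r = 0.0;
    if (sd[i] > 0 && sd[j] > 0) {
      double cp = 0;
      for (int k = 0; k < n; ++k)
        cp += (X(k, i) - mean[i]) * (X(k, j) - mean[j]);
      r = cp / (sd[i] * sd[j]);
    }
    if (!R_finite(r) || r < 0) r = 0.0;
    Edge e; e.key = std::round(r * 1e12) / 1e12; e.i = i; e.j = j;
    edges.push_back(e);
  }
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.key != b.key) return a.key > b.key;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  int n_pos = 0;
  for (size_t k = 0; k < edges.size(); ++k) if (edges[k].key > 0) ++n_pos;

  int ns = svals.size();
  std::vector< std::vector<double> > glob(6, std::vector<double>(ns));
  std::vector< NumericMatrix > nodal;
  if (need_nodal)
    for (int q = 0; q < 4; ++q) nodal.push_back(NumericMatrix(p, ns));

  IntegerMatrix A(p, p);
  int added = 0;
  std::vector<double> bc(p), C(p);
  for (int k = 0; k < ns; ++k) {
    int ek = std::min(ecounts[k], n_pos);
    for (; added < ek; ++added) {       // nested: extend the edge set
      A(edges[added].i, edges[added].j) = 1;
      A(edges[added].j, edges[added].i) = 1;
    }
    AdjList nb = to_adjlist(A);
    GlobalStats g = global_stats(A, nb);
    glob[0][k] = g.Cp; glob[1][k] = g.Lp; glob[2][k] = g.Eglob;
    if (need_null) {
      double cp_rand, lp_rand;
      null_ensemble_cp_lp(A, n_null, n_swap_per_edge, cp_rand, lp_rand);
      double gam = cp_rand > 0 ? g.Cp / cp_rand : R_NaN;
      double lam = lp_rand > 0 ? g.Lp / lp_rand : R_NaN;
      glob[3][k] = gam; glob[4][k] = lam; glob[5][k] = gam / lam;
    } else {
      glob[3][k] = R_NaN; glob[4][k] = R_NaN; glob[5][k] = R_NaN;
    }
    if (need_nodal) {
      brandes(nb, bc);
      clustering(A, nb, C);
      std::vector<int> dist(p);
      for (int i = 0; i < p; ++i) {
        nodal[0](i, k) = (double)nb[i].size();   // degree
        nodal[1](i, k) = bc[i];                  // betweenness
        bfs(nb, i, dist);
        double esum = 0;
        for (int j = 0; j < p; ++j)
          if (j != i && dist[j] > 0) esum += 1.0 / dist[j];
        nodal[2](i, k) = p > 1 ? esum / (p - 1) : R_NaN;
        nodal[3](i, k) = local_eff_node(A, nb[i]);
      }
    }
  }

  NumericVector gauc(6);
  for (int q = 0; q < 6; ++q) gauc[q] = auc_suffix(glob[q], svals);
  gauc.attr("names") = CharacterVector::create(
    "Cp", "Lp", "Eglob", "gamma", "lambda", "sigma");
  List out = List::create(_["global"] = gauc);
  if (need_nodal) {
    NumericMatrix nauc(4, p);
    for (int q = 0; q < 4; ++q) {
      std::vector<double> y(ns);
      for (int i = 0; i < p; ++i) {
        for (int k = 0; k < ns; ++k) y[k] = nodal[q](i, k);
        nauc(q, i) = auc_suffix(y, svals);
      }
    }
    out["nodal"] = nauc;
  }
  return out;
}

// Cp and Lp of n_null degree-preserving rewired versions of A.
// [[Rcpp::export]]
NumericMatrix cpp_null_cp_lp(IntegerMatrix A, int n_null, int n_swap_per_edge) {
  NumericMatrix out(n_null, 2);
  for (int r = 0; r < n_null; ++r) {
    IntegerMatrix B = clone(A);
    rewire_in_place(B, n_swap_per_edge);
    AdjList nb = to_adjlist(B);
    GlobalStats g = global_stats(B, nb);
    out(r, 0) = g.Cp;
    out(r, 1) = g.Lp;
  }
  return out;
}
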