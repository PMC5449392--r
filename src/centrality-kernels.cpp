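#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Flat CSR adjacency built from a 0-based undirected edge list.
struct Graph {
  int n;
  std::vector<int> ptr, nbr;
};

static Graph make_graph(int n, const IntegerVector& from, const IntegerVector& to) {
  Graph g;
  g.n = n;
  const int m = from.size();
  std::vector<int> deg(n, 0);
  for (int i = 0; i < m; ++i) {
    if (from[i] < 0 || from[i] >= n || to[i] < 0 || to[i] >= n)
      stop("edge endpoint out of range");
    deg[from[i]]++;
    deg[to[i]]++;
  }
  g.ptr.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) g.ptr[i + 1] = g.ptr[i] + deg[i];
  g.nbr.resize(2 * (size_t)m);
  std::vector<int> pos(g.ptr.begin(), g.ptr.end() - 1);
  for (int i = 0; i < m; ++i) {
    g.nbr[pos[from[i]]++] = to[i];
    g.nbr[pos[to[i]]++] = from[i];
  }
  return g;
}

// Stress centrality: number of shortest paths passing through each node,
// counted over unordered source-target pairs (endpoints excluded).
// Brandes-style accumulation: for source s, npaths[v] counts shortest-path
// continuations from v to any target below it in the BFS DAG, and the
// contribution of v is sigma(s,v) * npaths[v].
// [[Rcpp::export]]
NumericVector stress_kernel(int n, IntegerVector from, IntegerVector to) {
  Graph g = make_graph(n, from, to);
  NumericVector stress(n, 0.0);
  std::vector<int> dist(n);
  std::vector<int> order;
  order.reserve(n);
  std::vector<double> sigma(n), npaths(n);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    order.clear();
    int qh = 0, qt = 0;
    dist[s] = 0;
    sigma[s] = 1.0;
    q[qt++] = s;
    while (qh < qt) {
      int v = q[qh++];
      order.push_back(v);
      for (int j = g.ptr[v]; j < g.ptr[v + 1]; ++j) {
        int w = g.nbr[j];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q[qt++] = w;
        }
        if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
      }
    }
    std::fill(npaths.begin(), npaths.end(), 0.0);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int w = order[i];
      for (int j = g.ptr[w]; j < g.ptr[w + 1]; ++j) {
        int v = g.nbr[j];
        if (dist[v] == dist[w] - 1) npaths[v] += 1.0 + npaths[w];
      }
      stress[w] += sigma[w] * npaths[w];
    }
  }
  for (int i = 0; i < n; ++i) stress[i] /= 2.0;  // each unordered pair seen twice
  return stress;
}

// Centroid value: centroid(v) = min over u != v of gamma_v(u) - gamma_u(v),
// where gamma_v(u) = |{w != u,v : d(w,v) < d(w,u)}|. Takes the full
// shortest-path distance matrix (hops).
// [[Rcpp::export]]
NumericVector centroid_kernel(IntegerMatrix D) {
  const int n = D.nrow();
  if (D.ncol() != n) stop("distance matrix must be square");
  if (n < 2) stop("need at least two nodes");
  std::vector<unsigned char> Db((size_t)n * n);
  for (int v = 0; v < n; ++v)
    for (int w = 0; w < n; ++w) {
      int d = D(w, v);
      if (d < 0 || d > 250) stop("invalid distance (diameter limit 250)");
      Db[(size_t)v * n + w] = (unsigned char)d;  // column-v layout: d(w, v)
    }
  std::vector<int> fmin(n, INT_MAX);
  for (int v = 0; v < n; ++v) {
    const unsigned char* dv = &Db[(size_t)v * n];
    for (int u = v + 1; u < n; ++u) {
      const unsigned char* du = &Db[(size_t)u * n];
      int closer_v = 0, closer_u = 0;
      for (int w = 0; w < n; ++w) {
        closer_v += (du[w] > dv[w]);
        closer_u += (du[w] < dv[w]);
      }
      // drop w == v (strictly closer to v) and w == u (strictly closer to u)
      closer_v -= 1;
      closer_u -= 1;
      int f = closer_v - closer_u;
      if (f < fmin[v]) fmin[v] = f;
      if (-f < fmin[u]) fmin[u] = -f;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fmin[i];
  return out;
}

// Vulnerability: V_v = (E - E_v) / E with E the global efficiency (mean
// inverse distance over ordered pairs) and E_v the efficiency of the graph
// with v deleted, averaged over the remaining (n-1)(n-2) ordered pairs.
//
// Exact fast algorithm: one all-pairs BFS records distances and
// shortest-path counts. Removing v changes d(s,t) only when *every*
// shortest s-t path crosses v, i.e. d(s,v)+d(v,t)=d(s,t) and
// sigma(s,v)*sigma(v,t)=sigma(s,t). Only those targets are re-relaxed in
// the punctured graph, seeded by the (unchanged) distances of unaffected
// neighbours. Path counts are exact in doubles below 2^53; guarded.
// [[Rcpp::export]]
NumericVector vulnerability_kernel(int n, IntegerVector from, IntegerVector to) {
  Graph g = make_graph(n, from, to);
  if (n < 3) stop("vulnerability needs at least three nodes");
  const unsigned char UNSEEN = 255;
  std::vector<unsigned char> D((size_t)n * n, UNSEEN);
  std::vector<double> Sig((size_t)n * n, 0.0);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    unsigned char* ds = &D[(size_t)s * n];
    double* ss = &Sig[(size_t)s * n];
    int qh = 0, qt = 0;
    ds[s] = 0;
    ss[s] = 1.0;
    q[qt++] = s;
    while (qh < qt) {
      int v = q[qh++];
      if (ds[v] >= 250) stop("graph diameter exceeds 250");
      for (int j = g.ptr[v]; j < g.ptr[v + 1]; ++j) {
        int w = g.nbr[j];
        if (ds[w] == UNSEEN) {
          ds[w] = ds[v] + 1;
          q[qt++] = w;
        }
        if (ds[w] == ds[v] + 1) ss[w] += ss[v];
      }
    }
    for (int t = 0; t < n; ++t)
      if (ss[t] > 9.0e15)
        stop("shortest-path count exceeds exact double range");
  }
  double Etot = 0.0;
  std::vector<double> rowsum(n, 0.0);
  for (int s = 0; s < n; ++s) {
    const unsigned char* ds = &D[(size_t)s * n];
    double acc = 0.0;
    for (int t = 0; t < n; ++t)
      if (t != s && ds[t] != UNSEEN) acc += 1.0 / ds[t];
    rowsum[s] = acc;
    Etot += acc;
  }
  const double E_full = Etot / ((double)n * (n - 1));
  NumericVector vul(n);
  std::vector<int> aff;
  aff.reserve(n);
  std::vector<int> dnew(n, 0);
  std::vector<int> stamp(n, -1);
  const int INF = 1 << 29;
  // byte mask marking candidate targets (v on *some* shortest s-t path);
  // scanned 8 bytes at a time, then the exact all-paths test via sigma
  const size_t nw = ((size_t)n + 7) / 8;
  std::vector<unsigned char> cand(nw * 8, 0);
  for (int v = 0; v < n; ++v) {
    const unsigned char* dv = &D[(size_t)v * n];
    const double* sv = &Sig[(size_t)v * n];
    double corr = 0.0;  // ordered-pair sum of 1/d_old - 1/d_new
    for (int s = 0; s < n; ++s) {
      if (s == v) continue;
      const unsigned char* ds = &D[(size_t)s * n];
      const double* ssg = &Sig[(size_t)s * n];
      const double s_sv = ssg[v];
      if (s_sv == 0.0) continue;  // v unreachable from s
      const unsigned char dsv = ds[v];
      for (int t = 0; t < n; ++t)
        cand[t] = (ds[t] == (unsigned char)(dsv + dv[t]));
      cand[s] = 0;
      cand[v] = 0;
      aff.clear();
      const unsigned long long* words =
          reinterpret_cast<const unsigned long long*>(cand.data());
      for (size_t wi = 0; wi < nw; ++wi) {
        if (!words[wi]) continue;
        const int base = (int)(wi * 8);
        const int lim = std::min(8, n - base);
        for (int off = 0; off < lim; ++off) {
          const int t = base + off;
          if (cand[t] && ssg[t] == s_sv * sv[t]) aff.push_back(t);
        }
      }
      if (aff.empty()) continue;
      for (int t : aff) {
        stamp[t] = s;
        dnew[t] = INF;
      }
      std::sort(aff.begin(), aff.end(),
                [&](int a, int b) { return ds[a] < ds[b]; });
      bool changed = true;
      while (changed) {
        changed = false;
        for (int t : aff) {
          int best = dnew[t];
          for (int j = g.ptr[t]; j < g.ptr[t + 1]; ++j) {
            int u = g.nbr[j];
            if (u == v) continue;
            int du = (stamp[u] == s) ? dnew[u] : (int)ds[u];
            if (du + 1 < best) best = du + 1;
          }
          if (best < dnew[t]) {
            dnew[t] = best;
            changed = true;
          }
        }
      }
      for (int t : aff) {
        corr += 1.0 / ds[t] - (dnew[t] >= INF ? 0.0 : 1.0 / dnew[t]);
        stamp[t] = -1;
      }
    }
    const double Ev =
        (Etot - 2.0 * rowsum[v] - corr) / ((double)(n - 1) * (n - 2));
    vul[v] = (E_full - Ev) / E_full;
  }
  return vul;
}
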