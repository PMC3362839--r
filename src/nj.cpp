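// Neighbour-joining (Saitou & Nei agglomeration) on a full distance matrix.
// Returns the unrooted tree as an ape-style edge matrix. Kept in C++ because
// bootstrap pipelines call it tens of thousands of times.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Tie-break for equal Q values: the pair whose (sorted) label pair is
// lexicographically smallest wins; internal nodes inherit the smaller label
// of the pair they merged. This makes the agglomeration order a pure
// function of the input.
static bool pair_less(const std::string &a1, const std::string &a2,
                      const std::string &b1, const std::string &b2) {
  const std::string &alo = a1 < a2 ? a1 : a2, &ahi = a1 < a2 ? a2 : a1;
  const std::string &blo = b1 < b2 ? b1 : b2, &bhi = b1 < b2 ? b2 : b1;
  if (alo != blo) return alo < blo;
  return ahi < bhi;
}

// [[Rcpp::export(name = ".nj_cpp")]]
List nj_cpp(NumericMatrix dist, CharacterVector labels) {
  const int n = dist.nrow();
  if (n < 4) stop("nj_cpp requires at least 4 taxa");

  std::vector<std::vector<double> > d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = dist(i, j);

  std::vector<int> node(n);          // phylo node id of each active row
  std::vector<std::string> lab(n);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) {
    node[i] = i + 1;                 // tips are 1..n
    lab[i] = as<std::string>(labels[i]);
    active[i] = i;
  }

  const int n_internal = n - 2;
  // internal created k-th (k = 1..n-2) gets final id n + (n_internal - k) + 1
  // so the last one (the basal trichotomy) is the root id n + 1.
  int created = 0;
  const int n_edge = 2 * n - 3;
  IntegerMatrix edge(n_edge, 2);
  NumericVector elen(n_edge);
  int ei = 0;

  int m = n;                         // number of active clusters
  while (m > 3) {
    // row sums over active clusters
    std::vector<double> r(m, 0.0);
    for (int a = 0; a < m; ++a) {
      double s = 0.0;
      for (int b = 0; b < m; ++b) s += d[active[a]][active[b]];
      r[a] = s;
    }
    // minimise Q(a,b) = (m-2) d(a,b) - r_a - r_b
    int bi = -1, bj = -1;
    double bq = R_PosInf;
    for (int a = 0; a < m; ++a) {
      for (int b = a + 1; b < m; ++b) {
        double q = (m - 2) * d[active[a]][active[b]] - r[a] - r[b];
        if (q < bq ||
            (q == bq && bi >= 0 &&
             pair_less(lab[active[a]], lab[active[b]],
                       lab[active[bi]], lab[active[bj]]))) {
          bq = q; bi = a; bj = b;
        }
      }
    }
    const int ia = active[bi], ib = active[bj];
    double la = 0.5 * d[ia][ib] + (r[bi] - r[bj]) / (2.0 * (m - 2));
    double lb = d[ia][ib] - la;
    // clamp negative estimates to zero, moving the deficit to the sibling
    if (la < 0) { lb += la; la = 0; }
    if (lb < 0) { la += lb; lb = 0; }
    if (la < 0) la = 0;

    ++created;
    const int u = n + (n_internal - created) + 1;
    edge(ei, 0) = u; edge(ei, 1) = node[ia]; elen[ei] = la; ++ei;
    edge(ei, 0) = u; edge(ei, 1) = node[ib]; elen[ei] = lb; ++ei;

    // new cluster replaces slot ia; drop slot ib
    for (int c = 0; c < m; ++c) {
      const int ic = active[c];
      if (ic == ia || ic == ib) continue;
      const double nd = 0.5 * (d[ia][ic] + d[ib][ic] - d[ia][ib]);
      d[ia][ic] = d[ic][ia] = nd;
    }
    node[ia] = u;
    lab[ia] = lab[ia] < lab[ib] ? lab[ia] : lab[ib];
    active.erase(active.begin() + bj);
    --m;
  }

  // final three clusters join at the root trichotomy (id n + 1)
  const int a = active[0], b = active[1], c = active[2];
  const double xa = 0.5 * (d[a][b] + d[a][c] - d[b][c]);
  const double xb = 0.5 * (d[a][b] + d[b][c] - d[a][c]);
  const double xc = 0.5 * (d[a][c] + d[b][c] - d[a][b]);
  const int root = n + 1;
  edge(ei, 0) = root; edge(ei, 1) = node[a];
  elen[ei] = xa < 0 ? 0 : xa; ++ei;
  edge(ei, 0) = root; edge(ei, 1) = node[b];
  elen[ei] = xb < 0 ? 0 : xb; ++ei;
  edge(ei, 0) = root; edge(ei, 1) = node[c];
  elen[ei] = xc < 0 ? 0 : xc; ++ei;

  return List::create(_["edge"] = edge, _["edge.length"] = elen,
                      _["Nnode"] = n_internal);
}
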