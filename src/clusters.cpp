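#include <Rcpp.h>
using namespace Rcpp;

// Face-adjacency (6-neighbour) connected-component labelling over the
// valid voxels of a 3D grid. voxIndex holds, per valid voxel, its 0-based
// linear index into the full grid (x + nx*(y + ny*t)).
// [[Rcpp::export]]
IntegerVector label_clusters_cpp(LogicalVector supra, IntegerVector voxIndex,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nt = dims[2];
  const int V = supra.size();
  const long G = (long)nx * ny * nt;
  std::vector<int> gridmap(G, -1);
  for (int v = 0; v < V; v++) gridmap[voxIndex[v]] = v;
  IntegerVector labels(V, 0);
  int cur = 0;
  std::vector<int> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dt[6] = {0, 0, 0, 0, 1, -1};
  for (int v = 0; v < V; v++) {
    if (!supra[v] || labels[v]) continue;
    labels[v] = ++cur;
    stack.push_back(v);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      long gi = voxIndex[u];
      int x = gi % nx;
      long r = gi / nx;
      int y = r % ny;
      int t = r / ny;
      for (int k = 0; k < 6; k++) {
        int xx = x + dx[k], yy = y + dy[k], tt = t + dt[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || tt < 0 || tt >= nt)
          continue;
        long gj = xx + (long)nx * (yy + (long)ny * tt);
        int w = gridmap[gj];
        if (w >= 0 && supra[w] && !labels[w]) {
          labels[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Max-cluster-mass permutation null. contrasts: n_subjects x V matrix of
// per-subject contrast values at the valid voxels; signs: n_perm x
// n_subjects matrix of +/-1. For each permutation the voxel-wise
// one-sample F statistic (n * mean^2 / var, df 1, n-1) is computed from
// the sign-flipped contrasts, thresholded, labelled under 6-connectivity,
// and the heaviest summed-F cluster mass recorded (0 when no voxel is
// suprathreshold). Sum of squares per voxel is sign-invariant and
// precomputed.
// [[Rcpp::export]]
NumericVector perm_null_max_mass(NumericMatrix contrasts,
                                 IntegerVector voxIndex, IntegerVector dims,
                                 double fThresh, IntegerMatrix signs) {
  const int n = contrasts.nrow(), V = contrasts.ncol();
  const int nPerm = signs.nrow();
  const int nx = dims[0], ny = dims[1], nt = dims[2];
  const long G = (long)nx * ny * nt;
  std::vector<int> gridmap(G, -1);
  for (int v = 0; v < V; v++) gridmap[voxIndex[v]] = v;
  std::vector<double> ss(V, 0.0);
  for (int v = 0; v < V; v++) {
    double a = 0.0;
    for (int s = 0; s < n; s++) a += contrasts(s, v) * contrasts(s, v);
    ss[v] = a;
  }
  std::vector<double> F(V);
  std::vector<int> seen(V, -1);   // permutation stamp
  std::vector<int> stack;
  NumericVector out(nPerm);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dt[6] = {0, 0, 0, 0, 1, -1};
  for (int p = 0; p < nPerm; p++) {
    // voxel-wise F under this sign flip
    for (int v = 0; v < V; v++) {
      double m = 0.0;
      for (int s = 0; s < n; s++) m += signs(p, s) * contrasts(s, v);
      m /= n;
      double varn = (ss[v] - n * m * m) / (n - 1);
      if (varn > 1e-300) F[v] = n * m * m / varn;
      else F[v] = (std::fabs(m) > 1e-150) ? 1e12 : 0.0;
    }
    double best = 0.0;
    for (int v = 0; v < V; v++) {
      if (F[v] <= fThresh || seen[v] == p) continue;
      double mass = 0.0;
      seen[v] = p;
      stack.push_back(v);
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        mass += F[u];
        long gi = voxIndex[u];
        int x = gi % nx;
        long r = gi / nx;
        int y = r % ny;
        int t = r / ny;
        for (int k = 0; k < 6; k++) {
          int xx = x + dx[k], yy = y + dy[k], tt = t + dt[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || tt < 0 || tt >= nt)
            continue;
          long gj = xx + (long)nx * (yy + (long)ny * tt);
          int w = gridmap[gj];
          if (w >= 0 && F[w] > fThresh && seen[w] != p) {
            seen[w] = p;
            stack.push_back(w);
          }
        }
      }
      if (mass > best) best = mass;
    }
    out[p] = best;
  }
  return out;
}
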