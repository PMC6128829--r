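// DBSCAN and the Monte-Carlo parameter-sweep hot loop.
//
// Semantics: a point is a core point iff at least minPts points (itself
// included) lie within distance eps of it; clusters are maximal
// density-connected sets of core points plus their border points; a border
// point joins the first core cluster that reaches it in deterministic input
// order. Noise is labelled 0, clusters 1..k.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static std::vector<int> dbscan_run(const std::vector<double>& d2,
                                   int n, double eps, int minpts) {
  const double eps2 = eps * eps;
  std::vector<int> degree(n, 0);
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    const double* row = &d2[(size_t)i * n];
    for (int j = 0; j < n; ++j) if (row[j] <= eps2) ++cnt;
    degree[i] = cnt;  // includes the point itself (d2 == 0)
  }
  std::vector<int> label(n, 0);
  int cluster = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (label[i] != 0 || degree[i] < minpts) continue;
    ++cluster;
    label[i] = cluster;
    q.push(i);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      const double* row = &d2[(size_t)p * n];
      for (int j = 0; j < n; ++j) {
        if (row[j] > eps2 || label[j] != 0) continue;
        label[j] = cluster;                 // first cluster to reach j wins
        if (degree[j] >= minpts) q.push(j); // only core points expand
      }
    }
  }
  return label;
}

static std::vector<double> pairwise_d2(const NumericMatrix& pts) {
  const int n = pts.nrow();
  std::vector<double> d2((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    d2[(size_t)i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double v = dx * dx + dy * dy;
      d2[(size_t)i * n + j] = v;
      d2[(size_t)j * n + i] = v;
    }
  }
  return d2;
}

// distance from point (px, py) to segment (x1,y1)-(x2,y2)
static double seg_dist(double px, double py,
                       double x1, double y1, double x2, double y2) {
  double vx = x2 - x1, vy = y2 - y1;
  double len2 = vx * vx + vy * vy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - x1) * vx + (py - y1) * vy) / len2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double dx = px - (x1 + t * vx), dy = py - (y1 + t * vy);
  return std::sqrt(dx * dx + dy * dy);
}

static double polyline_dist(double px, double py, const NumericMatrix& segs) {
  double best = R_PosInf;
  for (int s = 0; s < segs.nrow(); ++s) {
    double d = seg_dist(px, py, segs(s, 0), segs(s, 1), segs(s, 2), segs(s, 3));
    if (d < best) best = d;
  }
  return best;
}

// [[Rcpp::export(name = ".dbscan_labels_cpp")]]
IntegerVector dbscan_labels_cpp(NumericMatrix pts, double eps, int minpts) {
  const int n = pts.nrow();
  if (n == 0) return IntegerVector(0);
  std::vector<double> d2 = pairwise_d2(pts);
  std::vector<int> lab = dbscan_run(d2, n, eps, minpts);
  return IntegerVector(lab.begin(), lab.end());
}

// One moving-window evaluation of the parameter sweep. `segs` holds the
// terminus polylines as rows (x1, y1, x2, y2); `rule` 0 attributes a cluster
// to the plume when its centroid lies within `buffer` of a terminus, rule 1
// when at least `member_frac` of its members do (per-point distances in
// `pt_term_dist`).
// [[Rcpp::export(name = ".dbscan_sweep_cpp")]]
List dbscan_sweep_cpp(NumericMatrix pts, NumericVector eps,
                      IntegerVector minpts, NumericMatrix segs,
                      double buffer, int rule, double member_frac,
                      NumericVector pt_term_dist) {
  const int n = pts.nrow();
  const int ndraw = eps.size();
  IntegerVector n_clusters(ndraw);
  LogicalVector plume_found(ndraw);
  NumericVector frac_in(ndraw);
  if (n == 0) {
    std::fill(frac_in.begin(), frac_in.end(), 0.0);
    return List::create(_["n_clusters"] = n_clusters,
                        _["plume_found"] = plume_found,
                        _["frac_in_clusters"] = frac_in);
  }
  std::vector<double> d2 = pairwise_d2(pts);
  for (int t = 0; t < ndraw; ++t) {
    std::vector<int> lab = dbscan_run(d2, n, eps[t], minpts[t]);
    int k = 0, in_cluster = 0;
    for (int i = 0; i < n; ++i) {
      if (lab[i] > k) k = lab[i];
      if (lab[i] > 0) ++in_cluster;
    }
    n_clusters[t] = k;
    frac_in[t] = (double)in_cluster / n;
    bool found = false;
    if (k > 0) {
      std::vector<double> cx(k, 0.0), cy(k, 0.0);
      std::vector<int> cn(k, 0), cnear(k, 0);
      for (int i = 0; i < n; ++i) {
        if (lab[i] == 0) continue;
        int c = lab[i] - 1;
        cx[c] += pts(i, 0); cy[c] += pts(i, 1); ++cn[c];
        if (pt_term_dist[i] <= buffer) ++cnear[c];
      }
      for (int c = 0; c < k && !found; ++c) {
        if (rule == 0) {
          double d = polyline_dist(cx[c] / cn[c], cy[c] / cn[c], segs);
          found = d <= buffer;
        } else {
          found = ((double)cnear[c] / cn[c]) >= member_frac;
        }
      }
    }
    plume_found[t] = found;
  }
  return List::create(_["n_clusters"] = n_clusters,
                      _["plume_found"] = plume_found,
                      _["frac_in_clusters"] = frac_in);
}
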