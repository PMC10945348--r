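// Lightweight CART-style trees, bagged forests and stump boosting used by
// the model harness. Uses R's RNG (via unif_rand) so everything is
// reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node indices
  double value;     // leaf probability of class 1
};

// Best gini split over a random subset of features for the samples in idx.
bool best_split(const NumericMatrix& X, const IntegerVector& y,
                const std::vector<int>& idx, const std::vector<int>& feats,
                int min_node, int& best_f, double& best_thr) {
  const int n = idx.size();
  int pos = 0;
  for (int i : idx) pos += y[i];
  if (pos == 0 || pos == n) return false;
  const double parent_imp = 2.0 * pos * (n - pos) / (double)(n * n);
  double best_gain = 1e-12;
  bool found = false;
  std::vector<std::pair<double,int> > vals(n);
  for (int f : feats) {
    for (int r = 0; r < n; ++r) vals[r] = std::make_pair(X(idx[r], f), y[idx[r]]);
    std::sort(vals.begin(), vals.end());
    int lpos = 0;
    for (int r = 0; r < n - 1; ++r) {
      lpos += vals[r].second;
      if (vals[r].first == vals[r + 1].first) continue;
      const int nl = r + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const int rpos = pos - lpos;
      const double imp_l = 2.0 * lpos * (nl - lpos) / (double)(nl * nl);
      const double imp_r = 2.0 * rpos * (nr - rpos) / (double)(nr * nr);
      const double gain = parent_imp - (nl * imp_l + nr * imp_r) / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[r].first + vals[r + 1].first);
        found = true;
      }
    }
  }
  return found;
}

int build_node(const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int depth, int max_depth, int min_node,
               int mtry, std::vector<Node>& nodes) {
  const int n = idx.size();
  int pos = 0;
  for (int i : idx) pos += y[i];
  Node node;
  node.feature = -1;
  node.threshold = 0.0;
  node.left = node.right = -1;
  node.value = (double)pos / n;
  if ((max_depth > 0 && depth >= max_depth) || n < 2 * min_node ||
      pos == 0 || pos == n) {
    nodes.push_back(node);
    return nodes.size() - 1;
  }
  // Sample mtry features without replacement (R RNG).
  const int d = X.ncol();
  std::vector<int> feats(d);
  for (int f = 0; f < d; ++f) feats[f] = f;
  for (int f = 0; f < std::min(mtry, d); ++f) {
    int j = f + (int)(unif_rand() * (d - f));
    if (j >= d) j = d - 1;
    std::swap(feats[f], feats[j]);
  }
  feats.resize(std::min(mtry, d));
  int bf = -1; double bthr = 0.0;
  if (!best_split(X, y, idx, feats, min_node, bf, bthr)) {
    nodes.push_back(node);
    return nodes.size() - 1;
  }
  std::vector<int> lidx, ridx;
  for (int i : idx) {
    if (X(i, bf) <= bthr) lidx.push_back(i); else ridx.push_back(i);
  }
  if (lidx.empty() || ridx.empty()) {
    nodes.push_back(node);
    return nodes.size() - 1;
  }
  node.feature = bf;
  node.threshold = bthr;
  nodes.push_back(node);
  const int self = nodes.size() - 1;
  const int l = build_node(X, y, lidx, depth + 1, max_depth, min_node, mtry, nodes);
  const int r = build_node(X, y, ridx, depth + 1, max_depth, min_node, mtry, nodes);
  nodes[self].left = l;
  nodes[self].right = r;
  return self;
}

NumericMatrix flatten(const std::vector<Node>& nodes) {
  NumericMatrix out(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].value;
  }
  return out;
}

double tree_predict_row(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    node = (X(row, (int)tree(node, 0)) <= tree(node, 1))
      ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export]]
List cpp_build_forest(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                      int max_depth, int min_node) {
  RNGScope scope;
  const int n = X.nrow();
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;
    }
    std::vector<Node> nodes;
    build_node(X, y, idx, 0, max_depth, min_node, mtry, nodes);
    forest[t] = flatten(nodes);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List forest, NumericMatrix X) {
  const int n = X.nrow(), ntree = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = forest[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// Best decision stump for weighted +/-1 labels: maximizes |T - 2A| where
// A is the weighted label sum left of the threshold (see classic discrete
// AdaBoost derivations). Returns (feature, threshold, polarity, error).
// [[Rcpp::export]]
NumericVector cpp_best_stump(NumericMatrix X, NumericVector ysign,
                             NumericVector w) {
  const int n = X.nrow(), d = X.ncol();
  double T = 0.0, wtot = 0.0;
  for (int i = 0; i < n; ++i) { T += w[i] * ysign[i]; wtot += w[i]; }
  double best = -1.0, bthr = 0.0, bpol = 1.0;
  int bf = 0;
  std::vector<std::pair<double,double> > vals(n);
  for (int f = 0; f < d; ++f) {
    for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(i, f), w[i] * ysign[i]);
    std::sort(vals.begin(), vals.end());
    double A = 0.0;
    for (int r = 0; r < n - 1; ++r) {
      A += vals[r].second;
      if (vals[r].first == vals[r + 1].first) continue;
      const double score = T - 2.0 * A;  // correct = .5*(wtot + |score|)
      if (std::fabs(score) > best) {
        best = std::fabs(score);
        bthr = 0.5 * (vals[r].first + vals[r + 1].first);
        bpol = score >= 0 ? 1.0 : -1.0;
        bf = f;
      }
    }
  }
  const double err = 0.5 * (wtot - best) / wtot;
  return NumericVector::create(bf, bthr, bpol, err);
}

// Discrete AdaBoost with decision stumps. Returns a (rounds x 4) matrix of
// (feature, threshold, polarity, alpha); prediction is the signed margin.
// [[Rcpp::export]]
NumericMatrix cpp_adaboost(NumericMatrix X, IntegerVector y, int rounds) {
  const int n = X.nrow();
  NumericVector ysign(n), w(n, 1.0 / n);
  for (int i = 0; i < n; ++i) ysign[i] = y[i] == 1 ? 1.0 : -1.0;
  std::vector<double> feat, thr, pol, alpha;
  for (int m = 0; m < rounds; ++m) {
    NumericVector st = cpp_best_stump(X, ysign, w);
    double err = st[3];
    if (err >= 0.5 - 1e-10) break;
    if (err < 1e-10) err = 1e-10;
    const double a = 0.5 * std::log((1.0 - err) / err);
    feat.push_back(st[0]); thr.push_back(st[1]); pol.push_back(st[2]);
    alpha.push_back(a);
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) {
      const double h = (X(i, (int)st[0]) > st[1]) ? st[2] : -st[2];
      w[i] *= std::exp(-a * ysign[i] * h);
      wsum += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= wsum;
    if (err < 1e-8) break;  // perfect stump: margin already decisive
  }
  NumericMatrix out(feat.size(), 4);
  for (size_t m = 0; m < feat.size(); ++m) {
    out(m, 0) = feat[m]; out(m, 1) = thr[m]; out(m, 2) = pol[m]; out(m, 3) = alpha[m];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_adaboost(NumericMatrix model, NumericMatrix X) {
  const int n = X.nrow(), M = model.nrow();
  NumericVector out(n);
  for (int m = 0; m < M; ++m) {
    const int f = (int)model(m, 0);
    for (int i = 0; i < n; ++i) {
      const double h = (X(i, f) > model(m, 1)) ? model(m, 2) : -model(m, 2);
      out[i] += model(m, 3) * h;
    }
  }
  return out;
}

// Friedman's LogitBoost with regression stumps on the working response.
// Returns (rounds x 4): (feature, threshold, left_value, right_value);
// F(x) = sum of 0.5 * leaf values, p = 1/(1+exp(-2F)).
// [[Rcpp::export]]
NumericMatrix cpp_logitboost(NumericMatrix X, IntegerVector y, int rounds) {
  const int n = X.nrow(), d = X.ncol();
  const double zmax = 4.0, wmin = 1e-5;
  NumericVector F(n, 0.0);
  std::vector<double> feat, thr, lv, rv;
  std::vector<std::pair<double,int> > ord(n);
  for (int m = 0; m < rounds; ++m) {
    // Working response and weights.
    std::vector<double> w(n), z(n);
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-2.0 * F[i]));
      double wi = p * (1.0 - p);
      if (wi < wmin) wi = wmin;
      double zi = (y[i] - p) / wi;
      if (zi > zmax) zi = zmax;
      if (zi < -zmax) zi = -zmax;
      w[i] = wi; z[i] = zi;
    }
    // Best weighted least-squares stump.
    double best_sse = R_PosInf, bthr = 0.0, blv = 0.0, brv = 0.0;
    int bf = -1;
    for (int f = 0; f < d; ++f) {
      for (int i = 0; i < n; ++i) ord[i] = std::make_pair(X(i, f), i);
      std::sort(ord.begin(), ord.end());
      double sw = 0.0, swz = 0.0, swz2 = 0.0;
      for (int i = 0; i < n; ++i) {
        sw += w[i]; swz += w[i] * z[i]; swz2 += w[i] * z[i] * z[i];
      }
      double lw = 0.0, lwz = 0.0, lwz2 = 0.0;
      for (int r = 0; r < n - 1; ++r) {
        const int i = ord[r].second;
        lw += w[i]; lwz += w[i] * z[i]; lwz2 += w[i] * z[i] * z[i];
        if (ord[r].first == ord[r + 1].first) continue;
        const double rw = sw - lw, rwz = swz - lwz, rwz2 = swz2 - lwz2;
        if (lw <= 0 || rw <= 0) continue;
        const double sse = (lwz2 - lwz * lwz / lw) + (rwz2 - rwz * rwz / rw);
        if (sse < best_sse) {
          best_sse = sse;
          bf = f;
          bthr = 0.5 * (ord[r].first + ord[r + 1].first);
          blv = lwz / lw;
          brv = rwz / rw;
        }
      }
    }
    if (bf < 0) break;  // all features constant
    feat.push_back(bf); thr.push_back(bthr); lv.push_back(blv); rv.push_back(brv);
    for (int i = 0; i < n; ++i) {
      F[i] += 0.5 * ((X(i, bf) <= bthr) ? blv : brv);
    }
  }
  NumericMatrix out(feat.size(), 4);
  for (size_t m = 0; m < feat.size(); ++m) {
    out(m, 0) = feat[m]; out(m, 1) = thr[m]; out(m, 2) = lv[m]; out(m, 3) = rv[m];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_logitboost(NumericMatrix model, NumericMatrix X) {
  const int n = X.nrow(), M = model.nrow();
  NumericVector F(n);
  for (int m = 0; m < M; ++m) {
    const int f = (int)model(m, 0);
    for (int i = 0; i < n; ++i) {
      F[i] += 0.5 * ((X(i, f) <= model(m, 1)) ? model(m, 2) : model(m, 3));
    }
  }
  NumericVector p(n);
  for (int i = 0; i < n; ++i) p[i] = 1.0 / (1.0 + std::exp(-2.0 * F[i]));
  return p;
}
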