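// k-means under the city-block (L1) metric with component-wise median
// centroid updates. All randomness flows through R's RNG so results are
// reproducible with set.seed(). Data are held feature-major (P x n) so the
// inner distance loops run over contiguous memory.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double l1_dist_ptr(const double* a, const double* b, int P) {
  double s = 0.0;
  for (int q = 0; q < P; ++q) s += std::fabs(a[q] - b[q]);
  return s;
}

// lower median: element at 0-based index floor((m-1)/2) of the sorted values
static double lower_median(std::vector<double>& v) {
  size_t nth = (v.size() - 1) / 2;
  std::nth_element(v.begin(), v.begin() + nth, v.end());
  return v[nth];
}

// nearest centroid, ties broken toward the lowest centroid index
static int nearest(const double* x, const mat& Ct, double* dist_out) {
  const int P = Ct.n_rows, k = Ct.n_cols;
  int best = 0;
  double bestd = l1_dist_ptr(x, Ct.colptr(0), P);
  for (int c = 1; c < k; ++c) {
    double d = l1_dist_ptr(x, Ct.colptr(c), P);
    if (d < bestd) { bestd = d; best = c; }
  }
  if (dist_out) *dist_out = bestd;
  return best;
}

// k-means++-style seeding under L1: first centre uniform, subsequent
// centres drawn with probability proportional to the L1 distance to the
// nearest chosen centre. Returns P x k centroids.
static mat kpp_init(const mat& Xt, int k) {
  const int n = Xt.n_cols, P = Xt.n_rows;
  mat Ct(P, k);
  int first = std::min(n - 1, (int)std::floor(unif_rand() * n));
  Ct.col(0) = Xt.col(first);
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) d[i] = l1_dist_ptr(Xt.colptr(i), Ct.colptr(0), P);
  for (int c = 1; c < k; ++c) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += d[i];
    int pick;
    if (total <= 0) {
      pick = std::min(n - 1, (int)std::floor(unif_rand() * n));
    } else {
      double u = unif_rand() * total, cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += d[i];
        if (u <= cum) { pick = i; break; }
      }
    }
    Ct.col(c) = Xt.col(pick);
    for (int i = 0; i < n; ++i)
      d[i] = std::min(d[i], l1_dist_ptr(Xt.colptr(i), Ct.colptr(c), P));
  }
  return Ct;
}

static Rcpp::List kmeans_l1_single(const mat& Xt, mat Ct, int max_iter) {
  const int n = Xt.n_cols, P = Xt.n_rows, k = Ct.n_cols;
  std::vector<int> labels(n, 0);
  std::vector<double> dists(n, 0.0);
  std::vector<double> obj_trace;
  std::vector<double> buf;
  double obj = datum::inf;

  for (int iter = 0; iter < max_iter; ++iter) {
    // assignment step
    std::vector<int> counts(k, 0);
    for (int i = 0; i < n; ++i) {
      labels[i] = nearest(Xt.colptr(i), Ct, &dists[i]);
      ++counts[labels[i]];
    }

    // empty clusters: re-seed at the point farthest from its centroid
    for (int c = 0; c < k; ++c) {
      if (counts[c] == 0) {
        int far = (int)(std::max_element(dists.begin(), dists.end()) - dists.begin());
        Ct.col(c) = Xt.col(far);
        --counts[labels[far]];
        labels[far] = c;
        counts[c] = 1;
        dists[far] = 0.0;
      }
    }

    // update step: component-wise (lower) median per cluster
    for (int c = 0; c < k; ++c) {
      if (counts[c] == 0) continue;
      for (int q = 0; q < P; ++q) {
        buf.clear();
        for (int i = 0; i < n; ++i)
          if (labels[i] == c) buf.push_back(Xt(q, i));
        Ct(q, c) = lower_median(buf);
      }
    }

    double new_obj = 0.0;
    for (int i = 0; i < n; ++i)
      new_obj += l1_dist_ptr(Xt.colptr(i), Ct.colptr(labels[i]), P);
    obj_trace.push_back(new_obj);
    if (std::fabs(obj - new_obj) < 1e-12) { obj = new_obj; break; }
    obj = new_obj;
  }

  // final assignment consistent with the returned centroids
  double final_obj = 0.0;
  for (int i = 0; i < n; ++i) {
    labels[i] = nearest(Xt.colptr(i), Ct, &dists[i]);
    final_obj += dists[i];
  }

  Rcpp::IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = labels[i] + 1;
  return Rcpp::List::create(
    Rcpp::Named("labels") = lab,
    Rcpp::Named("centroids") = mat(Ct.t()),
    Rcpp::Named("objective") = final_obj,
    Rcpp::Named("obj_trace") = obj_trace);
}

// [[Rcpp::export]]
Rcpp::List kmeans_l1_cpp(const arma::mat& X, int k, int n_replicates,
                         int max_iter,
                         Rcpp::Nullable<Rcpp::NumericMatrix> init) {
  Rcpp::RNGScope scope;
  mat Xt = X.t();
  if (init.isNotNull()) {
    mat c0 = Rcpp::as<mat>(Rcpp::NumericMatrix(init));
    return kmeans_l1_single(Xt, c0.t(), max_iter);
  }
  Rcpp::List best;
  double best_obj = datum::inf;
  for (int r = 0; r < n_replicates; ++r) {
    mat c0 = kpp_init(Xt, k);
    Rcpp::List fit = kmeans_l1_single(Xt, c0, max_iter);
    double obj = fit["objective"];
    if (obj < best_obj) { best_obj = obj; best = fit; }
  }
  return best;
}

// Mean silhouette width under L1 distances, plus per-point widths.
// a(i) = mean distance to own cluster (excluding self); b(i) = min over
// other clusters of the mean distance; s(i) = (b-a)/max(a,b), with s(i)=0
// for singletons and for the degenerate a=b=0 case.
// [[Rcpp::export]]
Rcpp::List silhouette_l1_cpp(const arma::mat& X, const arma::ivec& labels,
                             int k) {
  const int n = X.n_rows;
  mat Xt = X.t();
  const int P = Xt.n_rows;
  mat acc(n, k, fill::zeros);   // sum of distances from i to cluster c
  vec csize(k, fill::zeros);
  for (int i = 0; i < n; ++i) csize[labels[i] - 1] += 1.0;

  for (int i = 0; i < n; ++i) {
    const double* xi = Xt.colptr(i);
    for (int j = i + 1; j < n; ++j) {
      double d = l1_dist_ptr(xi, Xt.colptr(j), P);
      acc(i, labels[j] - 1) += d;
      acc(j, labels[i] - 1) += d;
    }
  }

  vec s(n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    int own = labels[i] - 1;
    if (csize[own] <= 1) { s[i] = 0.0; continue; }
    double a = acc(i, own) / (csize[own] - 1.0);
    double b = datum::inf;
    for (int c = 0; c < k; ++c) {
      if (c == own || csize[c] == 0) continue;
      b = std::min(b, acc(i, c) / csize[c]);
    }
    double m = std::max(a, b);
    s[i] = (m > 0) ? (b - a) / m : 0.0;
  }
  return Rcpp::List::create(Rcpp::Named("widths") = s,
                            Rcpp::Named("mean") = mean(s));
}
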