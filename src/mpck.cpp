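#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Diagonal-metric MPCK-Means inner loop.
//
// Cost model per point i assigned to cluster h:
//   d_Ah(x_i, mu_h) - log det(A_h)
// plus, for every must-link (i,j) violated (labels differ):
//   w_ml * 0.5 * (d_Ali(x_i,x_j) + d_Alj(x_i,x_j))
// and for every cannot-link (i,j) violated (labels equal, = h):
//   w_cl * (maxd_Ah - d_Ah(x_i,x_j))
// where d_A is the squared Euclidean distance weighted by the cluster's
// diagonal metric A_h and maxd_Ah = sum_d a_hd * range_d^2 bounds d_A over
// the data, so the cannot-link penalty is non-negative.
//
// The E-step is a sequential single-point sweep with immediate updates
// (ICM), the M-step recomputes centroids as cluster means and, when metric
// learning is on, sets each diagonal entry to its exact per-dimension
// minimiser n_h / (scatter + violation terms).  Every step is a coordinate
// descent move on the same objective, so the recorded objective trace is
// non-increasing.
//
// Data are kept in flat row-major buffers: the d-dimensional distance
// kernel runs over contiguous memory for every point and centre.

struct Flat {
  std::vector<double> v;
  int d;
  double *row(int i) { return v.data() + (size_t)i * d; }
  const double *row(int i) const { return v.data() + (size_t)i * d; }
};

static inline double wdist(const double *x, const double *mu,
                           const double *a, int d) {
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    double diff = x[c] - mu[c];
    s += a[c] * diff * diff;
  }
  return s;
}

// [[Rcpp::export(name = ".mpck_core")]]
List mpck_core(NumericMatrix X, NumericMatrix centers0,
               IntegerMatrix must, IntegerMatrix cannot,
               double w_ml, double w_cl,
               int max_iter, bool learn_metrics) {
  const int n = X.nrow(), d = X.ncol(), K = centers0.nrow();
  const double metric_floor = 1e-6, metric_cap = 1e6;

  Flat P; P.d = d; P.v.resize((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) P.v[(size_t)i * d + c] = X(i, c);
  Flat mu; mu.d = d; mu.v.resize((size_t)K * d);
  for (int h = 0; h < K; ++h)
    for (int c = 0; c < d; ++c) mu.v[(size_t)h * d + c] = centers0(h, c);
  Flat a; a.d = d; a.v.assign((size_t)K * d, 1.0);
  std::vector<double> logdet(K, 0.0), maxd(K, 0.0);

  // squared coordinate ranges of the whole data set, per dimension
  std::vector<double> g(d, 0.0);
  for (int c = 0; c < d; ++c) {
    double lo = P.v[c], hi = P.v[c];
    for (int i = 1; i < n; ++i) {
      double x = P.v[(size_t)i * d + c];
      if (x < lo) lo = x;
      if (x > hi) hi = x;
    }
    g[c] = (hi - lo) * (hi - lo);
  }
  for (int h = 0; h < K; ++h) {
    double s = 0.0;
    for (int c = 0; c < d; ++c) s += a.row(h)[c] * g[c];
    maxd[h] = s;
  }

  const int n_ml = must.nrow(), n_cl = cannot.nrow();
  std::vector<int> ml_a(n_ml), ml_b(n_ml), cl_a(n_cl), cl_b(n_cl);
  std::vector<std::vector<int> > ml_adj(n), cl_adj(n);
  for (int r = 0; r < n_ml; ++r) {
    ml_a[r] = must(r, 0); ml_b[r] = must(r, 1);
    ml_adj[ml_a[r]].push_back(ml_b[r]);
    ml_adj[ml_b[r]].push_back(ml_a[r]);
  }
  for (int r = 0; r < n_cl; ++r) {
    cl_a[r] = cannot(r, 0); cl_b[r] = cannot(r, 1);
    cl_adj[cl_a[r]].push_back(cl_b[r]);
    cl_adj[cl_b[r]].push_back(cl_a[r]);
  }

  // initial assignment: nearest centre under identity-initialised metrics
  std::vector<int> lab(n, 0);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int h = 0; h < K; ++h) {
      double c = wdist(P.row(i), mu.row(h), a.row(h), d) - logdet[h];
      if (c < best) { best = c; lab[i] = h; }
    }
  }

  std::vector<double> obj_trace;
  int iter = 0;
  bool changed = true;

  // run at least two iterations: the first E-step can coincide with the
  // initial assignment while the following M-step still moves parameters
  while ((changed || iter < 2) && iter < max_iter) {
    ++iter;
    changed = false;

    // E-step: sequential sweep, immediate updates
    for (int i = 0; i < n; ++i) {
      const double *xi = P.row(i);
      const bool has_con = !ml_adj[i].empty() || !cl_adj[i].empty();
      double best = R_PosInf;
      int best_h = lab[i];
      for (int h = 0; h < K; ++h) {
        double cost = wdist(xi, mu.row(h), a.row(h), d) - logdet[h];
        if (has_con) {
          for (size_t q = 0; q < ml_adj[i].size(); ++q) {
            int j = ml_adj[i][q];
            if (lab[j] != h)
              cost += w_ml * 0.5 *
                      (wdist(xi, P.row(j), a.row(h), d) +
                       wdist(xi, P.row(j), a.row(lab[j]), d));
          }
          for (size_t q = 0; q < cl_adj[i].size(); ++q) {
            int j = cl_adj[i][q];
            if (lab[j] == h) {
              double pen = maxd[h] - wdist(xi, P.row(j), a.row(h), d);
              if (pen > 0) cost += w_cl * pen;
            }
          }
        }
        if (cost < best) { best = cost; best_h = h; }
      }
      if (best_h != lab[i]) { lab[i] = best_h; changed = true; }
    }

    // M-step: centroids
    std::vector<int> cnt(K, 0);
    std::vector<double> sum((size_t)K * d, 0.0);
    for (int i = 0; i < n; ++i) {
      int h = lab[i];
      ++cnt[h];
      const double *xi = P.row(i);
      double *sh = sum.data() + (size_t)h * d;
      for (int c = 0; c < d; ++c) sh[c] += xi[c];
    }
    for (int h = 0; h < K; ++h)
      if (cnt[h] > 0)
        for (int c = 0; c < d; ++c)
          mu.v[(size_t)h * d + c] = sum[(size_t)h * d + c] / cnt[h];

    // M-step: per-cluster diagonal metrics (exact minimiser per dimension)
    if (learn_metrics) {
      std::vector<double> coef((size_t)K * d, 0.0);
      for (int i = 0; i < n; ++i) {
        int h = lab[i];
        const double *xi = P.row(i);
        const double *mh = mu.row(h);
        double *ch = coef.data() + (size_t)h * d;
        for (int c = 0; c < d; ++c) {
          double diff = xi[c] - mh[c];
          ch[c] += diff * diff;
        }
      }
      for (int r = 0; r < n_ml; ++r) {
        int i = ml_a[r], j = ml_b[r];
        if (lab[i] != lab[j]) {
          const double *xi = P.row(i), *xj = P.row(j);
          double *ci = coef.data() + (size_t)lab[i] * d;
          double *cj = coef.data() + (size_t)lab[j] * d;
          for (int c = 0; c < d; ++c) {
            double diff = xi[c] - xj[c];
            double t = w_ml * 0.5 * diff * diff;
            ci[c] += t;
            cj[c] += t;
          }
        }
      }
      for (int r = 0; r < n_cl; ++r) {
        int i = cl_a[r], j = cl_b[r];
        if (lab[i] == lab[j]) {
          const double *xi = P.row(i), *xj = P.row(j);
          double *ci = coef.data() + (size_t)lab[i] * d;
          for (int c = 0; c < d; ++c) {
            double diff = xi[c] - xj[c];
            ci[c] += w_cl * (g[c] - diff * diff);
          }
        }
      }
      for (int h = 0; h < K; ++h) {
        if (cnt[h] == 0) continue;
        double ld = 0.0, mx = 0.0;
        double *ah = a.row(h);
        const double *ch = coef.data() + (size_t)h * d;
        for (int c = 0; c < d; ++c) {
          double ac = cnt[h] / (ch[c] + 1e-12);
          if (ac < metric_floor) ac = metric_floor;
          if (ac > metric_cap) ac = metric_cap;
          ah[c] = ac;
          ld += std::log(ac);
          mx += ac * g[c];
        }
        logdet[h] = ld;
        maxd[h] = mx;
      }
    }

    // objective
    double obj = 0.0;
    for (int i = 0; i < n; ++i)
      obj += wdist(P.row(i), mu.row(lab[i]), a.row(lab[i]), d) -
             logdet[lab[i]];
    for (int r = 0; r < n_ml; ++r) {
      int i = ml_a[r], j = ml_b[r];
      if (lab[i] != lab[j])
        obj += w_ml * 0.5 * (wdist(P.row(i), P.row(j), a.row(lab[i]), d) +
                             wdist(P.row(i), P.row(j), a.row(lab[j]), d));
    }
    for (int r = 0; r < n_cl; ++r) {
      int i = cl_a[r], j = cl_b[r];
      if (lab[i] == lab[j]) {
        double pen = maxd[lab[i]] -
                     wdist(P.row(i), P.row(j), a.row(lab[i]), d);
        if (pen > 0) obj += w_cl * pen;
      }
    }
    obj_trace.push_back(obj);
  }

  NumericMatrix mu_out(K, d), a_out(K, d);
  for (int h = 0; h < K; ++h)
    for (int c = 0; c < d; ++c) {
      mu_out(h, c) = mu.row(h)[c];
      a_out(h, c) = a.row(h)[c];
    }
  IntegerVector lab_out(n);
  for (int i = 0; i < n; ++i) lab_out[i] = lab[i] + 1;

  return List::create(_["assignment"] = lab_out,
                      _["centroids"] = mu_out,
                      _["metric_weights"] = a_out,
                      _["objective"] = obj_trace.empty()
                          ? NA_REAL : obj_trace.back(),
                      _["obj_trace"] = NumericVector(obj_trace.begin(),
                                                     obj_trace.end()),
                      _["n_iter"] = iter);
}

// [[Rcpp::export(name = ".mpck_assign")]]
IntegerVector mpck_assign(NumericMatrix X, NumericMatrix centroids,
                          NumericMatrix metrics) {
  const int n = X.nrow(), d = X.ncol(), K = centroids.nrow();
  Flat P; P.d = d; P.v.resize((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) P.v[(size_t)i * d + c] = X(i, c);
  Flat mu; mu.d = d; mu.v.resize((size_t)K * d);
  Flat a; a.d = d; a.v.resize((size_t)K * d);
  std::vector<double> logdet(K, 0.0);
  for (int h = 0; h < K; ++h) {
    double ld = 0.0;
    for (int c = 0; c < d; ++c) {
      mu.v[(size_t)h * d + c] = centroids(h, c);
      a.v[(size_t)h * d + c] = metrics(h, c);
      ld += std::log(metrics(h, c));
    }
    logdet[h] = ld;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bh = 0;
    for (int h = 0; h < K; ++h) {
      double s = wdist(P.row(i), mu.row(h), a.row(h), d) - logdet[h];
      if (s < best) { best = s; bh = h; }
    }
    out[i] = bh + 1;
  }
  return out;
}
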