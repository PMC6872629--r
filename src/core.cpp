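#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Bilinear sampling with edge-clamped coordinates (0-based row/col).
// ---------------------------------------------------------------------------

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double sample_bilinear(const NumericMatrix& img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  r = clampd(r, 0.0, nr - 1.0);
  c = clampd(c, 0.0, nc - 1.0);
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 > nr - 2) r0 = nr - 2; if (r0 < 0) r0 = 0;
  if (c0 > nc - 2) c0 = nc - 2; if (c0 < 0) c0 = 0;
  const double fr = r - r0, fc = c - c0;
  if (nr == 1 && nc == 1) return img(0, 0);
  if (nr == 1) return (1 - fc) * img(0, c0) + fc * img(0, c0 + 1);
  if (nc == 1) return (1 - fr) * img(r0, 0) + fr * img(r0 + 1, 0);
  return (1 - fr) * ((1 - fc) * img(r0, c0)     + fc * img(r0, c0 + 1)) +
         fr       * ((1 - fc) * img(r0 + 1, c0) + fc * img(r0 + 1, c0 + 1));
}

// out(x) = img(x + u(x)) : pull warp on the grid of img.
// [[Rcpp::export(name = ".warp_pull_cpp")]]
NumericMatrix warp_pull_cpp(const NumericMatrix& img,
                            const NumericMatrix& ur,
                            const NumericMatrix& uc) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = sample_bilinear(img, i + ur(i, j), j + uc(i, j));
  return out;
}

// Resize a matrix by bilinear interpolation onto an nr2 x nc2 grid whose
// pixel centers are aligned with the source extent.
// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
NumericMatrix resize_bilinear_cpp(const NumericMatrix& img, int nr2, int nc2) {
  NumericMatrix out(nr2, nc2);
  const double sr = (double)img.nrow() / nr2, sc = (double)img.ncol() / nc2;
  for (int j = 0; j < nc2; ++j)
    for (int i = 0; i < nr2; ++i)
      out(i, j) = sample_bilinear(img, (i + 0.5) * sr - 0.5, (j + 0.5) * sc - 0.5);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, replicate-padded borders.
// ---------------------------------------------------------------------------

static std::vector<double> gauss_kernel(double sigma) {
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
NumericMatrix gauss_smooth_cpp(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  std::vector<double> k = gauss_kernel(sigma);
  const int rad = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // rows direction
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int o = -rad; o <= rad; ++o) {
        int ii = i + o; if (ii < 0) ii = 0; if (ii > nr - 1) ii = nr - 1;
        acc += k[o + rad] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  // cols direction
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int o = -rad; o <= rad; ++o) {
        int jj = j + o; if (jj < 0) jj = 0; if (jj > nc - 1) jj = nc - 1;
        acc += k[o + rad] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Demons iterations at a single resolution level.
// Update: v = diff * grad(ref) / (|grad(ref)|^2 + alpha^2 diff^2), v = 0 when
// the denominator < 1e-12; field <- smooth(field - v) each iteration.
// Stops early after 10 consecutive SSD increases; returns best field seen.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".demons_level_cpp")]]
List demons_level_cpp(const NumericMatrix& query, const NumericMatrix& ref,
                      NumericMatrix ur, NumericMatrix uc,
                      int iterations, double sigma, double alpha) {
  const int nr = ref.nrow(), nc = ref.ncol();
  // reference gradient: central differences, one-sided at borders
  NumericMatrix gr(nr, nc), gc(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (nr == 1) gr(i, j) = 0.0;
      else if (i == 0) gr(i, j) = ref(1, j) - ref(0, j);
      else if (i == nr - 1) gr(i, j) = ref(nr - 1, j) - ref(nr - 2, j);
      else gr(i, j) = 0.5 * (ref(i + 1, j) - ref(i - 1, j));
      if (nc == 1) gc(i, j) = 0.0;
      else if (j == 0) gc(i, j) = ref(i, 1) - ref(i, 0);
      else if (j == nc - 1) gc(i, j) = ref(i, nc - 1) - ref(i, nc - 2);
      else gc(i, j) = 0.5 * (ref(i, j + 1) - ref(i, j - 1));
    }
  NumericMatrix best_ur = clone(ur), best_uc = clone(uc);
  double best_ssd = R_PosInf, prev_ssd = R_PosInf;
  int n_increase = 0;
  bool diverged = false;
  const double a2 = alpha * alpha;
  for (int it = 0; it <= iterations; ++it) {
    NumericMatrix warped = warp_pull_cpp(query, ur, uc);
    double ssd = 0.0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        const double d = warped(i, j) - ref(i, j);
        ssd += d * d;
      }
    if (ssd < best_ssd) {
      best_ssd = ssd;
      best_ur = clone(ur);
      best_uc = clone(uc);
    }
    if (it > 0 && ssd > prev_ssd) {
      if (++n_increase >= 10) { diverged = true; break; }
    } else n_increase = 0;
    prev_ssd = ssd;
    if (it == iterations) break;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        const double d = warped(i, j) - ref(i, j);
        const double den = gr(i, j) * gr(i, j) + gc(i, j) * gc(i, j) + a2 * d * d;
        if (den >= 1e-12) {
          ur(i, j) -= d * gr(i, j) / den;
          uc(i, j) -= d * gc(i, j) / den;
        }
      }
    ur = gauss_smooth_cpp(ur, sigma);
    uc = gauss_smooth_cpp(uc, sigma);
  }
  return List::create(_["ur"] = best_ur, _["uc"] = best_uc,
                      _["ssd"] = best_ssd, _["diverged"] = diverged);
}

// ---------------------------------------------------------------------------
// Deterministic 2-means on the Gram matrix of the active feature subset.
// Farthest-pair seeding (lowest indices on ties), Lloyd fixed point capped at
// 100 iterations; quality = label agreement maximized over the two
// cluster<->label pairings. Degenerate (all rows identical) -> majority.
// ---------------------------------------------------------------------------

static double quality_from_gram(const std::vector<double>& G, int n,
                                const IntegerVector& lab, double majority,
                                double degen_tol) {
  // farthest pair
  int bi = -1, bj = -1;
  double bd = -1.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double d2 = G[i * n + i] + G[j * n + j] - 2.0 * G[i * n + j];
      if (d2 > bd + 1e-15) { bd = d2; bi = i; bj = j; }
    }
  if (bd < degen_tol) return majority;
  std::vector<int> a(n), anew(n);
  // initial assignment: nearer of the two seed rows (ties -> first seed)
  for (int k = 0; k < n; ++k) {
    const double di = G[k * n + k] - 2.0 * G[k * n + bi] + G[bi * n + bi];
    const double dj = G[k * n + k] - 2.0 * G[k * n + bj] + G[bj * n + bj];
    a[k] = (dj < di) ? 1 : 0;
  }
  for (int it = 0; it < 100; ++it) {
    int n0 = 0;
    for (int k = 0; k < n; ++k) if (a[k] == 0) ++n0;
    const int n1 = n - n0;
    if (n0 == 0 || n1 == 0) break;  // empty cluster: fixed point
    // centroid terms from the Gram matrix
    double S0 = 0.0, S1 = 0.0;
    std::vector<double> s0(n, 0.0), s1(n, 0.0);
    for (int i = 0; i < n; ++i) {
      const double* gi = &G[i * n];
      for (int j = 0; j < n; ++j) {
        if (a[j] == 0) s0[i] += gi[j]; else s1[i] += gi[j];
      }
      if (a[i] == 0) S0 += s0[i]; else S1 += s1[i];
    }
    bool changed = false;
    for (int k = 0; k < n; ++k) {
      const double d0 = -2.0 * s0[k] / n0 + S0 / ((double)n0 * n0);
      const double d1 = -2.0 * s1[k] / n1 + S1 / ((double)n1 * n1);
      anew[k] = (d1 < d0) ? 1 : 0;
      if (anew[k] != a[k]) changed = true;
    }
    a = anew;
    if (!changed) break;
  }
  int match = 0;
  for (int k = 0; k < n; ++k) if (a[k] == lab[k]) ++match;
  const int m2 = n - match;
  return (double)(match > m2 ? match : m2) / n;
}

// [[Rcpp::export(name = ".cluster_quality_cpp")]]
double cluster_quality_cpp(const NumericMatrix& X, const IntegerVector& lab) {
  const int n = X.nrow(), p = X.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += lab[i];
  const double majority = (double)std::max(n1, n - n1) / n;
  std::vector<double> G((size_t)n * n, 0.0);
  for (int f = 0; f < p; ++f)
    for (int i = 0; i < n; ++i) {
      const double xi = X(i, f);
      for (int j = 0; j < n; ++j) G[(size_t)i * n + j] += xi * X(j, f);
    }
  return quality_from_gram(G, n, lab, majority, 1e-9);
}

// One SFFS run (forward + backward pass) over a fixed feature ordering.
// Xexp: n x m expanded design (a circular feature may own 2 columns);
// feat_start/feat_len: CSR map feature -> expanded columns (0-based);
// ordering: 0-based permutation of features. Returns per-feature delta.
static void sffs_one_run(const NumericMatrix& Xexp,
                         const IntegerVector& feat_start,
                         const IntegerVector& feat_len,
                         const IntegerVector& lab, double majority,
                         const int* ordering, int p, int n,
                         std::vector<double>& G, IntegerVector& delta) {
  std::fill(G.begin(), G.end(), 0.0);
  double q = majority;
  // forward: add each feature in order (it stays regardless of outcome)
  for (int s = 0; s < p; ++s) {
    const int f = ordering[s];
    for (int c = 0; c < feat_len[f]; ++c) {
      const int col = feat_start[f] + c;
      for (int i = 0; i < n; ++i) {
        const double xi = Xexp(i, col);
        for (int j = 0; j < n; ++j) G[(size_t)i * n + j] += xi * Xexp(j, col);
      }
    }
    const double qn = quality_from_gram(G, n, lab, majority, 1e-9);
    delta[f] += (qn > q) ? 1 : -1;
    q = qn;
  }
  // backward: remove each feature in order until the subset is empty
  for (int s = 0; s < p; ++s) {
    const int f = ordering[s];
    for (int c = 0; c < feat_len[f]; ++c) {
      const int col = feat_start[f] + c;
      for (int i = 0; i < n; ++i) {
        const double xi = Xexp(i, col);
        for (int j = 0; j < n; ++j) G[(size_t)i * n + j] -= xi * Xexp(j, col);
      }
    }
    const double qn = (s == p - 1)
      ? majority
      : quality_from_gram(G, n, lab, majority, 1e-9);
    delta[f] += (qn < q) ? 1 : -1;
    q = qn;
  }
}

// [[Rcpp::export(name = ".sffs_runs_cpp")]]
IntegerVector sffs_runs_cpp(const NumericMatrix& Xexp,
                            const IntegerVector& feat_start,
                            const IntegerVector& feat_len,
                            const IntegerVector& lab,
                            const IntegerMatrix& orderings) {
  const int n = Xexp.nrow(), p = feat_start.size(), nruns = orderings.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += lab[i];
  const double majority = (double)std::max(n1, n - n1) / n;
  std::vector<double> G((size_t)n * n, 0.0);
  IntegerVector total(p);
  IntegerVector delta(p);
  std::vector<int> ord(p);
  for (int r = 0; r < nruns; ++r) {
    std::fill(delta.begin(), delta.end(), 0);
    for (int s = 0; s < p; ++s) ord[s] = orderings(s, r);
    sffs_one_run(Xexp, feat_start, feat_len, lab, majority, ord.data(), p, n, G, delta);
    for (int f = 0; f < p; ++f) total[f] += delta[f];
    if ((r & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return total;
}

// [[Rcpp::export(name = ".sffs_single_run_cpp")]]
IntegerVector sffs_single_run_cpp(const NumericMatrix& Xexp,
                                  const IntegerVector& feat_start,
                                  const IntegerVector& feat_len,
                                  const IntegerVector& lab,
                                  const IntegerVector& ordering) {
  const int n = Xexp.nrow(), p = feat_start.size();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += lab[i];
  const double majority = (double)std::max(n1, n - n1) / n;
  std::vector<double> G((size_t)n * n, 0.0);
  IntegerVector delta(p);
  std::vector<int> ord(p);
  for (int s = 0; s < p; ++s) ord[s] = ordering[s];
  sffs_one_run(Xexp, feat_start, feat_len, lab, majority, ord.data(), p, n, G, delta);
  return delta;
}
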