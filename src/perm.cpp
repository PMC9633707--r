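#include <Rcpp.h>
using namespace Rcpp;

// Draw a uniform index in [i, n): relies on R's RNG so set.seed() governs.
static inline int draw_idx(int i, int n) {
  int j = i + (int)(unif_rand() * (n - i));
  if (j >= n) j = n - 1;
  return j;
}

// [[Rcpp::export(name = ".perm_diff_engine")]]
List perm_diff_engine(NumericVector x, int n1, int n_perm) {
  int n = x.size();
  int n2 = n - n1;
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty");
  std::vector<double> xs(x.begin(), x.end());
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += xs[i];
  double s1 = 0.0;
  for (int i = 0; i < n1; ++i) s1 += xs[i];
  double obs = s1 / n1 - (total - s1) / n2;

  int ge = 0, le = 0, abs_ge = 0;
  double aobs = std::fabs(obs);
  // tie tolerance: summation order differs between permutations, so exact
  // ties drift by O(machine eps); count them as ties, which is conservative
  double tol = 1e-9 * (1.0 + aobs);
  for (int p = 0; p < n_perm; ++p) {
    // partial Fisher-Yates: first n1 entries become a uniform random subset
    for (int i = 0; i < n1; ++i) {
      int j = draw_idx(i, n);
      std::swap(xs[i], xs[j]);
    }
    double s = 0.0;
    for (int i = 0; i < n1; ++i) s += xs[i];
    double stat = s / n1 - (total - s) / n2;
    if (stat >= obs - tol) ++ge;
    if (stat <= obs + tol) ++le;
    if (std::fabs(stat) >= aobs - tol) ++abs_ge;
  }
  return List::create(_["observed"] = obs, _["n_ge"] = ge, _["n_le"] = le,
                      _["n_abs_ge"] = abs_ge, _["n_perm"] = n_perm);
}

static double com_delta(const std::vector<double> &m1,
                        const std::vector<double> &m2,
                        const std::vector<double> &gx,
                        const std::vector<double> &gy,
                        const std::vector<bool> &use) {
  double w1 = 0, x1 = 0, y1 = 0, w2 = 0, x2 = 0, y2 = 0;
  int k = (int)m1.size();
  for (int i = 0; i < k; ++i) {
    if (!use[i]) continue;
    double a = m1[i] > 0 ? m1[i] : 0.0;  // negative responses zeroed
    double b = m2[i] > 0 ? m2[i] : 0.0;
    w1 += a; x1 += a * gx[i]; y1 += a * gy[i];
    w2 += b; x2 += b * gx[i]; y2 += b * gy[i];
  }
  if (w1 <= 0 || w2 <= 0) return NA_REAL;
  double dx = x1 / w1 - x2 / w2, dy = y1 / w1 - y2 / w2;
  return std::sqrt(dx * dx + dy * dy);
}

// Null distribution of the across-session tuning center-of-mass shift,
// built by shuffling trials of the same whisker between the two sessions
// while preserving per-session trial counts.
// trials1/trials2: per-whisker numeric vectors of single-trial evoked dF/F,
// aligned element-wise with gx/gy (grid coordinates of each whisker).
// [[Rcpp::export(name = ".com_shuffle_engine")]]
NumericVector com_shuffle_engine(List trials1, List trials2,
                                 NumericVector gx, NumericVector gy,
                                 int n_iter) {
  int k = trials1.size();
  if (trials2.size() != k || gx.size() != k || gy.size() != k)
    stop("per-whisker inputs must align");
  std::vector<std::vector<double> > pool(k);
  std::vector<int> n1(k), ntot(k);
  std::vector<bool> use(k);
  for (int i = 0; i < k; ++i) {
    NumericVector a = trials1[i], b = trials2[i];
    n1[i] = a.size();
    ntot[i] = a.size() + b.size();
    use[i] = (a.size() > 0 && b.size() > 0);  // single-session whiskers dropped
    pool[i].reserve(ntot[i]);
    for (int j = 0; j < a.size(); ++j) pool[i].push_back(a[j]);
    for (int j = 0; j < b.size(); ++j) pool[i].push_back(b[j]);
  }
  std::vector<double> gxx(gx.begin(), gx.end()), gyy(gy.begin(), gy.end());
  std::vector<double> m1(k), m2(k), tot(k);
  for (int i = 0; i < k; ++i) {
    tot[i] = 0.0;
    for (size_t j = 0; j < pool[i].size(); ++j) tot[i] += pool[i][j];
  }
  NumericVector out(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < k; ++i) {
      if (!use[i]) { m1[i] = 0; m2[i] = 0; continue; }
      std::vector<double> &v = pool[i];
      int n = ntot[i], a = n1[i];
      for (int q = 0; q < a; ++q) {
        int j = draw_idx(q, n);
        std::swap(v[q], v[j]);
      }
      double s = 0.0;
      for (int q = 0; q < a; ++q) s += v[q];
      m1[i] = s / a;
      m2[i] = (tot[i] - s) / (n - a);
    }
    out[it] = com_delta(m1, m2, gxx, gyy, use);
  }
  return out;
}
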