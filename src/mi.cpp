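#include <Rcpp.h>
using namespace Rcpp;

// Plug-in mutual information (nats) from 1-based bin assignments, with a
// Miller-Madow bias correction and clamping at zero.  The correction term
// (m_xy - m_x - m_y + 1)/(2n) uses occupied-cell counts, the standard
// first-order bias of the plug-in entropy estimator.
static double mi_from_counts(const std::vector<int>& joint,
                             const std::vector<int>& rx,
                             const std::vector<int>& ry,
                             int B, int n) {
  double mi = 0.0;
  int m_xy = 0, m_x = 0, m_y = 0;
  const double dn = static_cast<double>(n);
  for (int i = 0; i < B; ++i) {
    if (rx[i] > 0) ++m_x;
    if (ry[i] > 0) ++m_y;
  }
  for (int i = 0; i < B; ++i) {
    if (rx[i] == 0) continue;
    for (int j = 0; j < B; ++j) {
      int c = joint[i * B + j];
      if (c == 0) continue;
      ++m_xy;
      double pxy = c / dn;
      mi += pxy * std::log(pxy * dn * dn / (static_cast<double>(rx[i]) * ry[j]));
    }
  }
  mi -= (m_xy - m_x - m_y + 1) / (2.0 * dn);
  return mi > 0.0 ? mi : 0.0;
}

static double mi_pair(const int* bx, const int* by, int B, int n,
                      std::vector<int>& joint, std::vector<int>& rx,
                      std::vector<int>& ry) {
  std::fill(joint.begin(), joint.end(), 0);
  std::fill(rx.begin(), rx.end(), 0);
  std::fill(ry.begin(), ry.end(), 0);
  for (int k = 0; k < n; ++k) {
    int i = bx[k] - 1, j = by[k] - 1;
    ++joint[i * B + j];
    ++rx[i];
    ++ry[j];
  }
  return mi_from_counts(joint, rx, ry, B, n);
}

// [[Rcpp::export(name = ".mi_bins_c")]]
double mi_bins_c(IntegerVector bx, IntegerVector by, int n_bins) {
  int n = bx.size();
  if (by.size() != n) stop("bin vectors must have equal length");
  std::vector<int> joint(n_bins * n_bins), rx(n_bins), ry(n_bins);
  return mi_pair(bx.begin(), by.begin(), n_bins, n, joint, rx, ry);
}

// MI for every (row1[k], row2[k]) pair of a genes x conditions bin matrix.
// [[Rcpp::export(name = ".mi_edges_c")]]
NumericVector mi_edges_c(IntegerMatrix bins, IntegerVector row1,
                         IntegerVector row2, int n_bins) {
  int n = bins.ncol();
  int m = row1.size();
  if (row2.size() != m) stop("edge index vectors must have equal length");
  NumericVector out(m);
  std::vector<int> joint(n_bins * n_bins), rx(n_bins), ry(n_bins);
  std::vector<int> bx(n), by(n);
  for (int e = 0; e < m; ++e) {
    int r1 = row1[e] - 1, r2 = row2[e] - 1;
    for (int k = 0; k < n; ++k) {
      bx[k] = bins(r1, k);
      by[k] = bins(r2, k);
    }
    out[e] = mi_pair(bx.data(), by.data(), n_bins, n, joint, rx, ry);
  }
  return out;
}

// Per-edge permutation null: the second profile's bins are shuffled n_perm
// times (Fisher-Yates on R's RNG stream) and the MI recomputed; returns the
// observed MI and the add-one permutation p-value for each edge.
// [[Rcpp::export(name = ".mi_perm_c")]]
List mi_perm_c(IntegerMatrix bins, IntegerVector row1, IntegerVector row2,
               int n_bins, int n_perm) {
  int n = bins.ncol();
  int m = row1.size();
  if (n_perm < 1) stop("n_perm must be >= 1");
  NumericVector mi_obs(m), pval(m);
  std::vector<int> joint(n_bins * n_bins), rx(n_bins), ry(n_bins);
  std::vector<int> bx(n), by(n), yperm(n);
  for (int e = 0; e < m; ++e) {
    int r1 = row1[e] - 1, r2 = row2[e] - 1;
    for (int k = 0; k < n; ++k) {
      bx[k] = bins(r1, k);
      by[k] = bins(r2, k);
    }
    double obs = mi_pair(bx.data(), by.data(), n_bins, n, joint, rx, ry);
    mi_obs[e] = obs;
    int ge = 0;
    yperm = by;
    for (int p = 0; p < n_perm; ++p) {
      for (int k = n - 1; k > 0; --k) {
        int j = static_cast<int>(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(yperm[k], yperm[j]);
      }
      double nullmi = mi_pair(bx.data(), yperm.data(), n_bins, n, joint, rx, ry);
      if (nullmi >= obs) ++ge;
    }
    pval[e] = (1.0 + ge) / (n_perm + 1.0);
    if (e % 64 == 0) checkUserInterrupt();
  }
  return List::create(_["mi"] = mi_obs, _["p_value"] = pval);
}
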