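#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-sided Wilcoxon rank-sum -log10(p) by the normal approximation
// with average ranks, tie variance correction and continuity
// correction. Returns NA when either genotype group is smaller than
// min_group; 0 when the variance degenerates (all values tied).
static double marker_lk(std::vector<std::pair<double, int> >& buf,
                        int min_group, double* n1o, double* n2o) {
  const int n = (int)buf.size();
  int n2 = 0;
  for (int i = 0; i < n; ++i) n2 += (buf[i].second == 2);
  const int n1 = n - n2;
  *n1o = n1; *n2o = n2;
  if (n1 < min_group || n2 < min_group) return NA_REAL;
  std::sort(buf.begin(), buf.end());
  double R2 = 0.0, tiesum = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && buf[j + 1].first == buf[i].first) ++j;
    const double t = j - i + 1;
    const double avg_rank = (i + j) / 2.0 + 1.0;  // 1-based average rank
    for (int k = i; k <= j; ++k)
      if (buf[k].second == 2) R2 += avg_rank;
    if (t > 1) tiesum += t * t * t - t;
    i = j + 1;
  }
  const double nn = n;
  const double mu = n2 * (nn + 1.0) / 2.0;
  const double var = (double)n1 * n2 / 12.0 *
    ((nn + 1.0) - tiesum / (nn * (nn - 1.0)));
  if (var <= 0.0) return 0.0;
  double z = (std::fabs(R2 - mu) - 0.5) / std::sqrt(var);
  if (z < 0.0) z = 0.0;
  double p = 2.0 * R::pnorm(-z, 0.0, 1.0, 1, 0);
  if (p > 1.0) p = 1.0;
  if (p <= 0.0) p = 1e-300;
  return -std::log10(p);
}

// geno: n x m integer matrix with values 1, 2 or NA; y: length n with
// no NA (filter upstream). Returns m x 3 matrix (lk, n1, n2).
// [[Rcpp::export]]
NumericMatrix ranksum_scan_cpp(IntegerMatrix geno, NumericVector y,
                               int min_group) {
  const int n = geno.nrow(), m = geno.ncol();
  if (y.size() != n) stop("genotype/trait dimension mismatch");
  NumericMatrix out(m, 3);
  std::vector<std::pair<double, int> > buf;
  buf.reserve(n);
  for (int j = 0; j < m; ++j) {
    buf.clear();
    for (int i = 0; i < n; ++i) {
      const int g = geno(i, j);
      if (g != NA_INTEGER) buf.push_back(std::make_pair(y[i], g));
    }
    double n1, n2;
    out(j, 0) = marker_lk(buf, min_group, &n1, &n2);
    out(j, 1) = n1;
    out(j, 2) = n2;
  }
  return out;
}

// subset rank-sum LK from global ranks (tie-free traits): the rank of
// a kept observation within the marker's non-missing subset is its
// global rank minus the number of dropped observations ranking below
// it, so no per-marker sorting is needed.
static double marker_lk_ranks(const int* gcol, const double* gr, int n,
                              const std::vector<double>& dropped_ranks,
                              int min_group) {
  const int dj = (int)dropped_ranks.size();
  double R2 = 0.0;
  int n1 = 0, n2 = 0;
  for (int i = 0; i < n; ++i) {
    const int g = gcol[i];
    if (g == NA_INTEGER) continue;
    if (g == 2) {
      const double r = gr[i];
      int c = 0;
      for (int d = 0; d < dj; ++d) c += (dropped_ranks[d] < r);
      R2 += r - c;
      ++n2;
    } else ++n1;
  }
  if (n1 < min_group || n2 < min_group) return NA_REAL;
  const double ns = n1 + n2;
  const double mu = n2 * (ns + 1.0) / 2.0;
  const double var = (double)n1 * n2 * (ns + 1.0) / 12.0;
  if (var <= 0.0) return 0.0;
  double z = (std::fabs(R2 - mu) - 0.5) / std::sqrt(var);
  if (z < 0.0) z = 0.0;
  double p = 2.0 * R::pnorm(-z, 0.0, 1.0, 1, 0);
  if (p > 1.0) p = 1.0;
  if (p <= 0.0) p = 1e-300;
  return -std::log10(p);
}

// Genome-wide maximum LK over defined markers for n_perm random
// permutations of y (R's RNG, so set.seed() controls reproducibility).
// [[Rcpp::export]]
NumericVector perm_max_lk_cpp(IntegerMatrix geno, NumericVector y,
                              int n_perm, int min_group) {
  const int n = geno.nrow(), m = geno.ncol();
  if (y.size() != n) stop("genotype/trait dimension mismatch");
  // global ranks of y; ties force the generic sorting path
  std::vector<double> ry(n);
  {
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return y[a] < y[b]; });
    for (int i = 0; i < n; ++i) ry[ord[i]] = i + 1;
  }
  bool has_ties = false;
  {
    std::vector<double> ys(y.begin(), y.end());
    std::sort(ys.begin(), ys.end());
    for (int i = 1; i < n; ++i)
      if (ys[i] == ys[i - 1]) { has_ties = true; break; }
  }
  // per-marker dropped-row lists
  std::vector<std::vector<int> > dropped(m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      if (geno(i, j) == NA_INTEGER) dropped[j].push_back(i);

  NumericVector out(n_perm);
  std::vector<double> yp(n), gr(n);
  std::vector<std::pair<double, int> > buf;
  buf.reserve(n);
  std::vector<double> drv;
  drv.reserve(n);
  for (int b = 0; b < n_perm; ++b) {
    IntegerVector perm = sample(n, n, false);  // 1-based, R RNG
    double mx = R_NegInf;
    bool any_def = false;
    if (!has_ties) {
      for (int i = 0; i < n; ++i) gr[i] = ry[perm[i] - 1];
      for (int j = 0; j < m; ++j) {
        drv.clear();
        for (size_t k = 0; k < dropped[j].size(); ++k)
          drv.push_back(gr[dropped[j][k]]);
        const double lk = marker_lk_ranks(&geno(0, j), gr.data(), n, drv,
                                          min_group);
        if (!ISNA(lk)) { any_def = true; if (lk > mx) mx = lk; }
      }
    } else {
      for (int i = 0; i < n; ++i) yp[i] = y[perm[i] - 1];
      for (int j = 0; j < m; ++j) {
        buf.clear();
        for (int i = 0; i < n; ++i) {
          const int g = geno(i, j);
          if (g != NA_INTEGER) buf.push_back(std::make_pair(yp[i], g));
        }
        double n1, n2;
        const double lk = marker_lk(buf, min_group, &n1, &n2);
        if (!ISNA(lk)) { any_def = true; if (lk > mx) mx = lk; }
      }
    }
    out[b] = any_def ? mx : NA_REAL;
  }
  return out;
}
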