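#include <Rcpp.h>
using namespace Rcpp;

// Local alignment with affine gaps.  Sequences arrive as 0-based integer
// codes into the rows/columns of the substitution matrix.  A gap of length
// L costs open + L * extend (the first gap position pays open + extend).

// [[Rcpp::export]]
double sw_score_int(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) return 0.0;
  const double first = gap_open + gap_extend;
  const double NEG = -1e300;
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0;      // H[i-1][j-1]
    double F = NEG;         // vertical gap state for current row
    double Hij_left = 0.0;  // H[i][j-1]
    std::vector<double> Hrow(n + 1, 0.0);
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(Hij_left - first, E[j] - gap_extend);
      F = std::max(H[j] - first, F - gap_extend);
      double h = diag + S(a[i - 1], b[j - 1]);
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0.0) h = 0.0;
      diag = H[j];
      Hrow[j] = h;
      Hij_left = h;
      if (h > best) best = h;
    }
    H = Hrow;
  }
  return best;
}

// Brute-force oracle: enumerate every local alignment path (runs of
// match/insert/delete columns over substring pairs) and keep the best
// running score.  Exponential; intended for tiny sequences in tests only.

static double enum_best;

static void enum_rec(const IntegerVector& a, const IntegerVector& b,
                     const NumericMatrix& S, double open, double ext,
                     int i, int j, double sc, int last) {
  if (sc > enum_best) enum_best = sc;
  const int m = a.size(), n = b.size();
  if (i < m && j < n)
    enum_rec(a, b, S, open, ext, i + 1, j + 1,
             sc + S(a[i], b[j]), 0);
  if (i < m)
    enum_rec(a, b, S, open, ext, i + 1, j,
             sc - (last == 1 ? ext : open + ext), 1);
  if (j < n)
    enum_rec(a, b, S, open, ext, i, j + 1,
             sc - (last == 2 ? ext : open + ext), 2);
}

// [[Rcpp::export]]
double sw_enum_int(IntegerVector a, IntegerVector b, NumericMatrix S,
                   double gap_open, double gap_extend) {
  enum_best = 0.0;  // the empty alignment
  const int m = a.size(), n = b.size();
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      enum_rec(a, b, S, gap_open, gap_extend, i + 1, j + 1,
               S(a[i], b[j]), 0);
  return enum_best;
}
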