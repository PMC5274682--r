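#include <Rcpp.h>
using namespace Rcpp;

// Local alignment of a DNA sequence against a cyclic 4 x n profile
// (the artificial periodic index sequence 1..n,1..n,... is never
// materialized; the profile column index runs modulo n).
//
// States, with i = consumed sequence prefix, j = last consumed column:
//   H(i,j): last step matched s[i] to column j
//   E(i,j): last step was an insertion (s[i] consumed, column held at j)
//   F(i,j): last step deleted column j
// Affine gaps: opening costs gap_open, each further step gap_extend.
// Alignments start and end in a match state; scores are floored at 0 by
// allowing H to restart.  Bases coded 1..4 (A,C,G,T), 0 = N (scores 0).
//
// F's recurrence chains cyclically within a row; two passes around the
// ring resolve it exactly because a deletion run of >= n columns costs
// >= gap_open + (n-1)*gap_extend and returns to the same column, so it
// never beats the run it wraps.

static const double NEG = -1e100;

// [[Rcpp::export]]
double cpp_score_periodic(IntegerVector s, NumericMatrix m,
                          double gap_open, double gap_extend) {
  const int N = s.size(), n = m.ncol();
  std::vector<double> Hp(n, NEG), Ep(n, NEG), Fp(n, NEG),
                      Hc(n), Ec(n), Fc(n);
  // row 0: nothing consumed; H/E/F undefined (restart handled via max(...,0))
  std::fill(Hp.begin(), Hp.end(), NEG);
  double best = 0.0;
  for (int i = 0; i < N; ++i) {
    const int b = s[i];
    for (int j = 0; j < n; ++j)
      Ec[j] = std::max(Hp[j] - gap_open, Ep[j] - gap_extend);
    for (int j = 0; j < n; ++j) {
      const int jm1 = (j == 0) ? n - 1 : j - 1;
      double prev = 0.0;
      if (Hp[jm1] > prev) prev = Hp[jm1];
      if (Ep[jm1] > prev) prev = Ep[jm1];
      if (Fp[jm1] > prev) prev = Fp[jm1];
      const double sc = (b > 0) ? m(b - 1, j) : 0.0;
      Hc[j] = sc + prev;
      if (Hc[j] > best) best = Hc[j];
    }
    std::fill(Fc.begin(), Fc.end(), NEG);
    for (int pass = 0; pass < 2; ++pass)
      for (int j = 0; j < n; ++j) {
        const int jm1 = (j == 0) ? n - 1 : j - 1;
        const double f = std::max(Hc[jm1] - gap_open, Fc[jm1] - gap_extend);
        if (f > Fc[j]) Fc[j] = f;
      }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  return best;
}

// [[Rcpp::export]]
List cpp_align_periodic(IntegerVector s, NumericMatrix m,
                        double gap_open, double gap_extend) {
  const int N = s.size(), n = m.ncol();
  if (N == 0)
    return List::create(_["score"] = 0.0,
                        _["op"] = IntegerVector(0),
                        _["seq_pos"] = IntegerVector(0),
                        _["col"] = IntegerVector(0));
  std::vector<std::vector<double> > H(N + 1, std::vector<double>(n, NEG)),
    E(N + 1, std::vector<double>(n, NEG)),
    F(N + 1, std::vector<double>(n, NEG));
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= N; ++i) {
    const int b = s[i - 1];
    for (int j = 0; j < n; ++j)
      E[i][j] = std::max(H[i - 1][j] - gap_open, E[i - 1][j] - gap_extend);
    for (int j = 0; j < n; ++j) {
      const int jm1 = (j == 0) ? n - 1 : j - 1;
      double prev = 0.0;
      if (H[i - 1][jm1] > prev) prev = H[i - 1][jm1];
      if (E[i - 1][jm1] > prev) prev = E[i - 1][jm1];
      if (F[i - 1][jm1] > prev) prev = F[i - 1][jm1];
      const double sc = (b > 0) ? m(b - 1, j) : 0.0;
      H[i][j] = sc + prev;
      if (H[i][j] > best) { best = H[i][j]; bi = i; bj = j; }
    }
    for (int pass = 0; pass < 2; ++pass)
      for (int j = 0; j < n; ++j) {
        const int jm1 = (j == 0) ? n - 1 : j - 1;
        const double f = std::max(H[i][jm1] - gap_open, F[i][jm1] - gap_extend);
        if (f > F[i][j]) F[i][j] = f;
      }
  }
  std::vector<int> op, seq_pos, col;            // op: 1 match, 2 ins, 3 del
  if (best > 0.0) {
    const double eps = 1e-9;
    int i = bi, j = bj; char st = 'H';
    while (true) {
      if (st == 'H') {
        const int b = s[i - 1];
        const double sc = (b > 0) ? m(b - 1, j) : 0.0;
        op.push_back(1); seq_pos.push_back(i); col.push_back(j + 1);
        const double v = H[i][j] - sc;
        const int jm1 = (j == 0) ? n - 1 : j - 1;
        if (v < eps) break;                      // restart: fresh local start
        // preference among predecessors: match > deletion > insertion
        if (i > 1 && std::abs(v - H[i - 1][jm1]) < eps) { --i; j = jm1; }
        else if (i >= 1 && std::abs(v - F[i - 1][jm1]) < eps) { --i; j = jm1; st = 'F'; }
        else if (i > 1 && std::abs(v - E[i - 1][jm1]) < eps) { --i; j = jm1; st = 'E'; }
        else break;                              // restart (v ~ 0)
        if (i < 1) break;
      } else if (st == 'F') {
        op.push_back(3); seq_pos.push_back(i); col.push_back(j + 1);
        const int jm1 = (j == 0) ? n - 1 : j - 1;
        if (std::abs(F[i][j] - (H[i][jm1] - gap_open)) < eps) { j = jm1; st = 'H'; }
        else j = jm1;
      } else {                                   // E
        op.push_back(2); seq_pos.push_back(i); col.push_back(j + 1);
        if (std::abs(E[i][j] - (H[i - 1][j] - gap_open)) < eps) { --i; st = 'H'; }
        else --i;
        if (i < 1) break;
      }
    }
    std::reverse(op.begin(), op.end());
    std::reverse(seq_pos.begin(), seq_pos.end());
    std::reverse(col.begin(), col.end());
  }
  return List::create(_["score"] = best,
                      _["op"] = wrap(op),
                      _["seq_pos"] = wrap(seq_pos),
                      _["col"] = wrap(col));
}
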