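#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic program over a scan-by-scan similarity matrix.
// Maximizes the summed similarity of matched scan pairs; off-diagonal moves
// (a scan of one profile left unmatched) cost gap_init to open and
// gap_extend to extend. Returns the matched (run scan, center scan) index
// pairs of the optimal path, 1-based, in ascending order. Ties prefer the
// diagonal so that self-alignment returns the identity.
// [[Rcpp::export(name = ".dp_align")]]
IntegerMatrix dp_align(NumericMatrix S, double gap_init, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // state 0 = M (match), 1 = X (gap: run scan skipped... advance i), 2 = Y (advance j)
  std::vector<double> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<signed char> pM((n + 1) * (m + 1), -1), pX(pM), pY(pM);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[at(i, 0)] = -gap_init - (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j)
    Y[at(0, j)] = -gap_init - (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal step consuming S[i-1][j-1]
      double d0 = M[at(i - 1, j - 1)], d1 = X[at(i - 1, j - 1)],
             d2 = Y[at(i - 1, j - 1)];
      double best = d0; signed char arg = 0;
      if (d1 > best) { best = d1; arg = 1; }
      if (d2 > best) { best = d2; arg = 2; }
      if (best > NEG / 2) {
        M[at(i, j)] = best + S(i - 1, j - 1);
        pM[at(i, j)] = arg;
      }
      // X: advance i (run scan unmatched)
      double xo = M[at(i - 1, j)] - gap_init;
      double xe = X[at(i - 1, j)] - gap_extend;
      if (xo >= xe) { X[at(i, j)] = xo; pX[at(i, j)] = 0; }
      else          { X[at(i, j)] = xe; pX[at(i, j)] = 1; }
      // Y: advance j (center scan unmatched)
      double yo = M[at(i, j - 1)] - gap_init;
      double ye = Y[at(i, j - 1)] - gap_extend;
      if (yo >= ye) { Y[at(i, j)] = yo; pY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ye; pY[at(i, j)] = 2; }
    }
  }

  int state = 0;
  double best = M[at(n, m)];
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }

  std::vector<int> mi, mj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && state == 0) {
      mi.push_back(i); mj.push_back(j);
      state = pM[at(i, j)];
      --i; --j;
    } else if (i > 0 && (j == 0 || state == 1)) {
      state = (j == 0) ? (i == 1 ? 0 : 1) : pX[at(i, j)];
      --i;
    } else {
      state = (i == 0) ? (j == 1 ? 0 : 2) : pY[at(i, j)];
      --j;
    }
  }
  IntegerMatrix out(mi.size(), 2);
  for (size_t k = 0; k < mi.size(); ++k) {
    out(mi.size() - 1 - k, 0) = mi[k];
    out(mi.size() - 1 - k, 1) = mj[k];
  }
  return out;
}
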