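#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming kernels for token and coordinate alignments.
//
// sw_affine_dp: Smith-Waterman with affine, element-specific gap penalties.
//   The penalty charged for a gap column is that of the token being
//   *skipped*: skipping target token j (gap in the query) costs
//   go_col[j] + ge_col[j] to open and ge_col[j] to extend; skipping query
//   token i costs go_row[i]/ge_row[i] analogously.
//   Tie-breaking is fixed so outputs are bit-stable: on equal scores the
//   cell recurrence prefers diagonal, then up (gap in target), then left
//   (gap in query); the traceback starts from the highest-scoring cell,
//   ties broken by smallest (row, col).
//
// nw_free_dp: sequence-order-respecting alignment with free end gaps and a
//   linear internal gap penalty, used by the TM-score alignment iteration.

// pointer codes
static const int P_STOP = 0, P_DIAG = 1, P_UP = 2, P_LEFT = 3;

// [[Rcpp::export]]
List sw_affine_dp(NumericMatrix S,
                  NumericVector go_row, NumericVector ge_row,
                  NumericVector go_col, NumericVector ge_col) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), R_NegInf); // gap in query (left)
  std::vector<double> F((n + 1) * (m + 1), R_NegInf); // gap in target (up)
  std::vector<signed char> ptrH((n + 1) * (m + 1), P_STOP);
  std::vector<signed char> extE((n + 1) * (m + 1), 0); // 1 = extension
  std::vector<signed char> extF((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double eo = H[at(i, j - 1)] + go_col[j - 1] + ge_col[j - 1];
      const double ee = E[at(i, j - 1)] + ge_col[j - 1];
      E[at(i, j)] = (ee > eo) ? ee : eo;          // prefer open on ties
      extE[at(i, j)] = (ee > eo) ? 1 : 0;
      const double fo = H[at(i - 1, j)] + go_row[i - 1] + ge_row[i - 1];
      const double fe = F[at(i - 1, j)] + ge_row[i - 1];
      F[at(i, j)] = (fe > fo) ? fe : fo;
      extF[at(i, j)] = (fe > fo) ? 1 : 0;

      const double d = H[at(i - 1, j - 1)] + S(i - 1, j - 1);
      double h = d;
      int p = P_DIAG;
      if (F[at(i, j)] > h) { h = F[at(i, j)]; p = P_UP; }
      if (E[at(i, j)] > h) { h = E[at(i, j)]; p = P_LEFT; }
      if (h <= 0.0) { h = 0.0; p = P_STOP; }
      H[at(i, j)] = h;
      ptrH[at(i, j)] = (signed char)p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> qi, tj;
  int i = bi, j = bj;
  // walk back through H/E/F states
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      const int p = ptrH[at(i, j)];
      if (p == P_STOP) break;
      if (p == P_DIAG) {
        qi.push_back(i); tj.push_back(j);
        --i; --j;
      } else if (p == P_UP) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // E: gap in query, consume target j
      qi.push_back(NA_INTEGER); tj.push_back(j);
      const bool ext = extE[at(i, j)] != 0;
      --j;
      if (!ext) state = 0;
    } else { // F: gap in target, consume query i
      qi.push_back(i); tj.push_back(NA_INTEGER);
      const bool ext = extF[at(i, j)] != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(tj.begin(), tj.end());

  return List::create(_["score"] = best,
                      _["qi"] = wrap(qi), _["tj"] = wrap(tj),
                      _["q_end"] = bi, _["t_end"] = bj);
}

// [[Rcpp::export]]
List nw_free_dp(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<signed char> P((n + 1) * (m + 1), P_STOP);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // end gaps free: gaps touching row 0 / col 0 or the final border cost 0
      const double gu = (j == m) ? 0.0 : gap;
      const double gl = (i == n) ? 0.0 : gap;
      double h = H[at(i - 1, j - 1)] + S(i - 1, j - 1);
      int p = P_DIAG;
      const double up = H[at(i - 1, j)] + ((j == 0) ? 0.0 : gu);
      if (up > h) { h = up; p = P_UP; }
      const double lf = H[at(i, j - 1)] + gl;
      if (lf > h) { h = lf; p = P_LEFT; }
      H[at(i, j)] = h;
      P[at(i, j)] = (signed char)p;
    }
  }

  std::vector<int> qi, tj;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    const int p = P[at(i, j)];
    if (p == P_DIAG) {
      qi.push_back(i); tj.push_back(j);
      --i; --j;
    } else if (p == P_UP) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(tj.begin(), tj.end());
  return List::create(_["score"] = H[at(n, m)],
                      _["qi"] = wrap(qi), _["tj"] = wrap(tj));
}
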