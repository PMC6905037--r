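#include <Rcpp.h>
using namespace Rcpp;

// Best local ungapped segment of an integer-encoded protein against a
// position-specific scoring matrix (rows = model columns, cols = 20 residues,
// bit units). Residue codes outside 1..20 (X, *, gaps) score 0. Returns the
// maximal segment score together with its span on the sequence and the model.
// [[Rcpp::export]]
List pssm_scan_c(NumericMatrix pssm, IntegerVector seq) {
  const int L = pssm.nrow();
  const int n = seq.size();
  const double *P = REAL(pssm);
  std::vector<double> prev(L + 1, 0.0), cur(L + 1, 0.0);
  std::vector<int> sprev(L + 1, 0), scur(L + 1, 0); // segment start (seq pos)
  double best = 0.0;
  int best_i = 0, best_j = 0, best_sj = 0;
  for (int j = 1; j <= n; ++j) {
    cur[0] = 0.0;
    scur[0] = j + 1;
    const int a = seq[j - 1];
    const double *col = (a >= 1 && a <= 20) ? P + (size_t)(a - 1) * L : nullptr;
    for (int i = 1; i <= L; ++i) {
      const double s = col ? col[i - 1] : 0.0;
      const double v = prev[i - 1] + s;
      if (v > 0.0) {
        cur[i] = v;
        scur[i] = (prev[i - 1] > 0.0) ? sprev[i - 1] : j;
      } else {
        cur[i] = 0.0;
        scur[i] = j + 1;
      }
      if (cur[i] > best) {
        best = cur[i];
        best_i = i;
        best_j = j;
        best_sj = scur[i];
      }
    }
    std::swap(prev, cur);
    std::swap(sprev, scur);
  }
  int seg_len = (best > 0.0) ? (best_j - best_sj + 1) : 0;
  int model_end = best_i, model_start = (best > 0.0) ? best_i - seg_len + 1 : 0;
  return List::create(_["score"] = best,
                      _["seq_start"] = (best > 0.0) ? best_sj : 0,
                      _["seq_end"] = best_j,
                      _["model_start"] = model_start,
                      _["model_end"] = model_end);
}

// Smith-Waterman local alignment score (affine gaps, score only).
// a, b: 1-based residue indices into `sub`; codes < 1 score `sub` row/col 0
// is not addressed, they contribute 0. Gap of length k costs open + k * ext.
// [[Rcpp::export]]
double sw_score_c(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double open, double ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double *S = REAL(sub);
  const int ns = sub.nrow();
  const int *pb = INTEGER(b);
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double Hdiag = 0.0; // H[i-1][j-1]
    double F = NEG;
    const int ai = a[i - 1];
    const double *row = (ai >= 1) ? S + (size_t)(ai - 1) : nullptr;
    for (int j = 1; j <= m; ++j) {
      const int bj = pb[j - 1];
      const double s =
          (row && bj >= 1) ? row[(size_t)(bj - 1) * ns] : 0.0;
      E[j] = std::max(E[j] - ext, H[j] - open - ext);
      F = std::max(F - ext, H[j - 1] - open - ext);
      double h = Hdiag + s;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0.0) h = 0.0;
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Global (Needleman-Wunsch) alignment path over a precomputed column-pair
// score matrix (used for profile-profile merges in the progressive aligner).
// Returns 1-based column indices of each profile along the merged alignment,
// 0 marking a gap column. Affine gaps: length-k gap costs open + k * ext.
// [[Rcpp::export]]
List nw_affine_path_c(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in second profile (consume row i), Y: gap in first (consume col j)
  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    X(i, 0) = -open - ext * i;
    Y(i, 0) = NEG;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = -open - ext * j;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double mm = std::max(std::max(M(i - 1, j - 1), X(i - 1, j - 1)),
                           Y(i - 1, j - 1));
      M(i, j) = mm + S(i - 1, j - 1);
      X(i, j) = std::max(M(i - 1, j) - open - ext, X(i - 1, j) - ext);
      Y(i, j) = std::max(M(i, j - 1) - open - ext, Y(i, j - 1) - ext);
    }
  }
  // traceback
  std::vector<int> ai, bj;
  int i = n, j = m;
  int state; // 0 = M, 1 = X, 2 = Y
  double vM = M(n, m), vX = X(n, m), vY = Y(n, m);
  state = (vM >= vX && vM >= vY) ? 0 : (vX >= vY ? 1 : 2);
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    if (j == 0) state = 1;
    if (state == 0) {
      ai.push_back(i);
      bj.push_back(j);
      double pM = M(i - 1, j - 1), pX = X(i - 1, j - 1), pY = Y(i - 1, j - 1);
      --i;
      --j;
      state = (pM >= pX && pM >= pY) ? 0 : (pX >= pY ? 1 : 2);
    } else if (state == 1) {
      ai.push_back(i);
      bj.push_back(0);
      double stay = X(i - 1, j) - ext, enter = M(i - 1, j) - open - ext;
      --i;
      state = (stay >= enter) ? 1 : 0;
    } else {
      ai.push_back(0);
      bj.push_back(j);
      double stay = Y(i, j - 1) - ext, enter = M(i, j - 1) - open - ext;
      --j;
      state = (stay >= enter) ? 2 : 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bj));
}
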