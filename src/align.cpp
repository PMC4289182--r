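#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh).  A gap of length k costs
// gap_open + gap_extend * (k - 1): the first gapped residue is charged the
// full opening penalty, each further residue the extension penalty.
//
// Sequences arrive as 1-based integer codes into the substitution matrix.
// States: 0 = M (a[i] aligned to b[j]), 1 = X (gap in b, consumes a, "up"),
// 2 = Y (gap in a, consumes b, "left").  All tie-breaks prefer M > X > Y
// (diagonal > up > left), which makes the traceback deterministic.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

inline int argmax3(double m, double x, double y) {
  // preference M > X > Y on ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".nw_align_c")]]
List nw_align_c(IntegerVector a, IntegerVector b, NumericMatrix mat,
                double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // predecessor state of each cell in each state
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pX((n + 1) * (m + 1), -1);
  std::vector<signed char> pY((n + 1) * (m + 1), -1);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = -(gap_open + gap_extend * (i - 1));
    pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = -(gap_open + gap_extend * (j - 1));
    pY[IDX(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const double *srow = &mat(a[i - 1] - 1, 0);
    const int nrow = mat.nrow();
    for (int j = 1; j <= m; ++j) {
      const double s = srow[(std::size_t)(b[j - 1] - 1) * nrow];
      // M
      double dm = M[IDX(i - 1, j - 1)], dx = X[IDX(i - 1, j - 1)],
             dy = Y[IDX(i - 1, j - 1)];
      int am = argmax3(dm, dx, dy);
      double best = (am == 0 ? dm : (am == 1 ? dx : dy));
      if (best > NEG_INF) {
        M[IDX(i, j)] = best + s;
        pM[IDX(i, j)] = (signed char)am;
      }
      // X: consume a[i]
      dm = M[IDX(i - 1, j)] - gap_open;
      dx = X[IDX(i - 1, j)] - gap_extend;
      dy = Y[IDX(i - 1, j)] - gap_open;
      am = argmax3(dm, dx, dy);
      best = (am == 0 ? dm : (am == 1 ? dx : dy));
      if (best > NEG_INF) {
        X[IDX(i, j)] = best;
        pX[IDX(i, j)] = (signed char)am;
      }
      // Y: consume b[j]
      dm = M[IDX(i, j - 1)] - gap_open;
      dx = X[IDX(i, j - 1)] - gap_open;
      dy = Y[IDX(i, j - 1)] - gap_extend;
      am = argmax3(dm, dx, dy);
      best = (am == 0 ? dm : (am == 1 ? dx : dy));
      if (best > NEG_INF) {
        Y[IDX(i, j)] = best;
        pY[IDX(i, j)] = (signed char)am;
      }
    }
  }

  int state = argmax3(M[IDX(n, m)], X[IDX(n, m)], Y[IDX(n, m)]);
  double score = (state == 0 ? M[IDX(n, m)]
                             : (state == 1 ? X[IDX(n, m)] : Y[IDX(n, m)]));

  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pM[IDX(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = pX[IDX(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i; state = prev;
    } else {
      int prev = pY[IDX(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
#undef IDX
  return List::create(_["score"] = score, _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}

// [[Rcpp::export(name = ".sw_score_c")]]
double sw_score_c(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  const double VERY_NEG = -1e30;
  const int nrow = mat.nrow();
  const double *M0 = REAL(mat);
  // per-column offsets into the (column-major) substitution matrix
  std::vector<std::size_t> bcol(m);
  for (int j = 0; j < m; ++j) bcol[j] = (std::size_t)(b[j] - 1) * nrow;
  std::vector<int> ai(n);
  for (int i = 0; i < n; ++i) ai[i] = a[i] - 1;

  std::vector<double> Mprev(m + 1, 0.0), Mcur(m + 1, 0.0);
  std::vector<double> Xprev(m + 1, VERY_NEG), Xcur(m + 1, VERY_NEG);
  std::vector<double> Yprev(m + 1, VERY_NEG), Ycur(m + 1, VERY_NEG);
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *srow = M0 + ai[i];
    double *mp = Mprev.data(), *mc = Mcur.data();
    double *xp = Xprev.data(), *xc = Xcur.data();
    double *yp = Yprev.data(), *yc = Ycur.data();
    mc[0] = 0.0;
    xc[0] = VERY_NEG;
    double y = VERY_NEG;
    for (int j = 1; j <= m; ++j) {
      const double s = srow[bcol[j - 1]];
      double x = mp[j] - gap_open;
      const double xe = xp[j] - gap_extend;
      if (xe > x) x = xe;
      double yo = mc[j - 1] - gap_open;
      y -= gap_extend;
      if (yo > y) y = yo;
      double diag = mp[j - 1];
      if (xp[j - 1] > diag) diag = xp[j - 1];
      if (yp[j - 1] > diag) diag = yp[j - 1];
      double mm = (diag > 0.0 ? diag : 0.0) + s;
      if (mm < 0.0) mm = 0.0;
      mc[j] = mm;
      xc[j] = x;
      yc[j] = y;
      if (mm > best) best = mm;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }
  return best;
}

// [[Rcpp::export(name = ".sw_align_c")]]
List sw_align_c(IntegerVector a, IntegerVector b, NumericMatrix mat,
                double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // predecessor states; for M, -2 marks a fresh (zero-floored) start
  std::vector<signed char> pM((n + 1) * (m + 1), -2);
  std::vector<signed char> pX((n + 1) * (m + 1), -1);
  std::vector<signed char> pY((n + 1) * (m + 1), -1);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))
  double best = 0.0;
  int bi_ = 0, bj_ = 0;
  const int nrow = mat.nrow();
  for (int i = 1; i <= n; ++i) {
    const double *srow = &mat(a[i - 1] - 1, 0);
    for (int j = 1; j <= m; ++j) {
      const double s = srow[(std::size_t)(b[j - 1] - 1) * nrow];
      double dm = M[IDX(i - 1, j - 1)], dx = X[IDX(i - 1, j - 1)],
             dy = Y[IDX(i - 1, j - 1)];
      int am = argmax3(dm, dx, dy);
      double d = (am == 0 ? dm : (am == 1 ? dx : dy));
      double mm;
      if (d <= 0.0) {       // nothing worth extending: start fresh here
        mm = s;
        pM[IDX(i, j)] = -2;
      } else {
        mm = d + s;
        pM[IDX(i, j)] = (signed char)am;
      }
      if (mm < 0.0) {
        mm = 0.0;
        pM[IDX(i, j)] = -2;
      }
      M[IDX(i, j)] = mm;
      dm = M[IDX(i - 1, j)] - gap_open;
      dx = X[IDX(i - 1, j)] - gap_extend;
      am = (dm >= dx) ? 0 : 1;
      X[IDX(i, j)] = (am == 0 ? dm : dx);
      pX[IDX(i, j)] = (signed char)am;
      dm = M[IDX(i, j - 1)] - gap_open;
      dy = Y[IDX(i, j - 1)] - gap_extend;
      am = (dm >= dy) ? 0 : 2;
      Y[IDX(i, j)] = (am == 0 ? dm : dy);
      pY[IDX(i, j)] = (signed char)am;
      if (M[IDX(i, j)] > best) {
        best = M[IDX(i, j)];
        bi_ = i; bj_ = j;
      }
    }
  }

  std::vector<int> ai, bi;
  if (best > 0.0) {
    int i = bi_, j = bj_, state = 0;
    while (true) {
      if (state == 0) {
        int prev = pM[IDX(i, j)];
        ai.push_back(i); bi.push_back(j);
        --i; --j;
        if (prev == -2) break;
        state = prev;
      } else if (state == 1) {
        int prev = pX[IDX(i, j)];
        ai.push_back(i); bi.push_back(0);
        --i; state = prev;
      } else {
        int prev = pY[IDX(i, j)];
        ai.push_back(0); bi.push_back(j);
        --j; state = prev;
      }
    }
    std::reverse(ai.begin(), ai.end());
    std::reverse(bi.begin(), bi.end());
  }
#undef IDX
  return List::create(_["score"] = best, _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}
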