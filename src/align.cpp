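#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap dynamic programming over a precomputed position-score matrix
// S (m x n), where S(i,j) is the score of pairing position i of the first
// profile/sequence with position j of the second. A gap of length L costs
// open + L * ext (the Biostrings/BLAST convention). Working on the score
// matrix rather than the raw sequences lets the same kernel serve pairwise
// (S = substitution lookups) and profile-profile (S = fA' %*% sub %*% fB)
// alignment.

static const double NEG = -std::numeric_limits<double>::infinity();

// state codes for traceback
enum { ST_M = 0, ST_X = 1, ST_Y = 2 };  // X: gap in second (consume i), Y: gap in first (consume j)

// [[Rcpp::export]]
List nw_affine_cpp(NumericMatrix S, double open, double ext) {
  int m = S.nrow(), n = S.ncol();
  std::vector<double> M((m + 1) * (n + 1), NEG), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  std::vector<signed char> tbM((m + 1) * (n + 1)), tbX((m + 1) * (n + 1)),
      tbY((m + 1) * (n + 1));
#define IDX(i, j) ((i) * (n + 1) + (j))
  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[IDX(i, 0)] = -(open + i * ext);
    tbX[IDX(i, 0)] = ST_X;
  }
  for (int j = 1; j <= n; ++j) {
    Y[IDX(0, j)] = -(open + j * ext);
    tbY[IDX(0, j)] = ST_Y;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M: consume both
      double best = M[IDX(i - 1, j - 1)];
      signed char st = ST_M;
      if (X[IDX(i - 1, j - 1)] > best) { best = X[IDX(i - 1, j - 1)]; st = ST_X; }
      if (Y[IDX(i - 1, j - 1)] > best) { best = Y[IDX(i - 1, j - 1)]; st = ST_Y; }
      M[IDX(i, j)] = best + S(i - 1, j - 1);
      tbM[IDX(i, j)] = st;
      // X: gap in second profile (consume i)
      double xo = M[IDX(i - 1, j)] - (open + ext);
      double xe = X[IDX(i - 1, j)] - ext;
      double yo = Y[IDX(i - 1, j)] - (open + ext);
      if (xo >= xe && xo >= yo) { X[IDX(i, j)] = xo; tbX[IDX(i, j)] = ST_M; }
      else if (xe >= yo)        { X[IDX(i, j)] = xe; tbX[IDX(i, j)] = ST_X; }
      else                      { X[IDX(i, j)] = yo; tbX[IDX(i, j)] = ST_Y; }
      // Y: gap in first profile (consume j)
      double ym = M[IDX(i, j - 1)] - (open + ext);
      double ye = Y[IDX(i, j - 1)] - ext;
      double yx = X[IDX(i, j - 1)] - (open + ext);
      if (ym >= ye && ym >= yx) { Y[IDX(i, j)] = ym; tbY[IDX(i, j)] = ST_M; }
      else if (ye >= yx)        { Y[IDX(i, j)] = ye; tbY[IDX(i, j)] = ST_Y; }
      else                      { Y[IDX(i, j)] = yx; tbY[IDX(i, j)] = ST_X; }
    }
  }
  double score = M[IDX(m, n)];
  int st = ST_M;
  if (X[IDX(m, n)] > score) { score = X[IDX(m, n)]; st = ST_X; }
  if (Y[IDX(m, n)] > score) { score = Y[IDX(m, n)]; st = ST_Y; }
  // traceback
  std::vector<int> ai, bi;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (st == ST_M) {
      int prev = tbM[IDX(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j; st = prev;
    } else if (st == ST_X) {
      int prev = tbX[IDX(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i; st = prev;
    } else {
      int prev = tbY[IDX(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j; st = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score, _["a"] = wrap(ai), _["b"] = wrap(bi));
#undef IDX
}

// [[Rcpp::export]]
List sw_affine_cpp(NumericMatrix S, double open, double ext) {
  int m = S.nrow(), n = S.ncol();
  std::vector<double> M((m + 1) * (n + 1), 0.0), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
#define IDX(i, j) ((i) * (n + 1) + (j))
  double best = 0.0;
  int bi_ = 0, bj_ = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double d = M[IDX(i - 1, j - 1)];
      if (X[IDX(i - 1, j - 1)] > d) d = X[IDX(i - 1, j - 1)];
      if (Y[IDX(i - 1, j - 1)] > d) d = Y[IDX(i - 1, j - 1)];
      double mm = d + S(i - 1, j - 1);
      if (mm < 0) mm = 0;  // local floor: restart
      M[IDX(i, j)] = mm;
      double x = M[IDX(i - 1, j)] - (open + ext);
      if (X[IDX(i - 1, j)] - ext > x) x = X[IDX(i - 1, j)] - ext;
      X[IDX(i, j)] = x;
      double y = M[IDX(i, j - 1)] - (open + ext);
      if (Y[IDX(i, j - 1)] - ext > y) y = Y[IDX(i, j - 1)] - ext;
      Y[IDX(i, j)] = y;
      if (mm > best) { best = mm; bi_ = i; bj_ = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  }
  // traceback from (bi_, bj_) in state M until the running score hits 0
  int i = bi_, j = bj_, st = ST_M;
  int ai0 = i, bj0 = j;
  while (i > 0 && j > 0) {
    if (st == ST_M) {
      if (M[IDX(i, j)] == 0) break;
      double d = M[IDX(i - 1, j - 1)];
      int prev = ST_M;
      if (X[IDX(i - 1, j - 1)] > d) { d = X[IDX(i - 1, j - 1)]; prev = ST_X; }
      if (Y[IDX(i - 1, j - 1)] > d) { d = Y[IDX(i - 1, j - 1)]; prev = ST_Y; }
      --i; --j;
      ai0 = i + 1; bj0 = j + 1;
      if (d <= 0) break;  // alignment started here
      st = prev;
    } else if (st == ST_X) {
      double xo = M[IDX(i - 1, j)] - (open + ext);
      double xe = X[IDX(i - 1, j)] - ext;
      st = (xo >= xe) ? ST_M : ST_X;
      --i;
    } else {
      double ym = M[IDX(i, j - 1)] - (open + ext);
      double ye = Y[IDX(i, j - 1)] - ext;
      st = (ym >= ye) ? ST_M : ST_Y;
      --j;
    }
  }
  // spans: 0-based half-open on original sequences
  return List::create(_["score"] = best,
                      _["a_start"] = ai0 - 1, _["a_end"] = bi_,
                      _["b_start"] = bj0 - 1, _["b_end"] = bj_);
#undef IDX
}
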