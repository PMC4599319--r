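#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh) over a precomputed
// column-vs-column score matrix. A gap run of length g costs
// open + (g - 1) * extend. States: M (diagonal), X (gap in the column
// sequence of B, i.e. consume a row of `score`), Y (gap in A, consume a
// column). Ties are broken deterministically: at every cell the
// preference order is M > X > Y, which makes the traceback prefer
// diagonal > up > left.
//
// Returns the optimal score and the alignment path as two integer
// vectors (1-based positions, 0 = gap).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix score, double gap_open, double gap_extend,
                 bool terminal_free) {
  const int n = score.nrow();
  const int m = score.ncol();
  // DP tables, (n+1) x (m+1), row-major flattened
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: which predecessor state (0=M,1=X,2=Y, -1 none)
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    double c = terminal_free ? 0.0 : -(gap_open + (i - 1) * gap_extend);
    X[at(i, 0)] = c;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    double c = terminal_free ? 0.0 : -(gap_open + (j - 1) * gap_extend);
    Y[at(0, j)] = c;
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal from best of (M, X, Y) at (i-1, j-1)
      {
        double vm = M[at(i - 1, j - 1)], vx = X[at(i - 1, j - 1)],
               vy = Y[at(i - 1, j - 1)];
        double best = vm; signed char who = 0;
        if (vx > best) { best = vx; who = 1; }
        if (vy > best) { best = vy; who = 2; }
        if (best > NEG_INF) {
          M[at(i, j)] = best + score(i - 1, j - 1);
          tbM[at(i, j)] = who;
        }
      }
      // X: gap in B (consume a_i); free at j == m if terminal_free
      {
        bool term = terminal_free && (j == m);
        double op = term ? 0.0 : gap_open;
        double ex = term ? 0.0 : gap_extend;
        double vm = M[at(i - 1, j)] == NEG_INF ? NEG_INF : M[at(i - 1, j)] - op;
        double vx = X[at(i - 1, j)] == NEG_INF ? NEG_INF : X[at(i - 1, j)] - ex;
        double vy = Y[at(i - 1, j)] == NEG_INF ? NEG_INF : Y[at(i - 1, j)] - op;
        double best = vm; signed char who = 0;
        if (vx > best) { best = vx; who = 1; }
        if (vy > best) { best = vy; who = 2; }
        if (best > NEG_INF) { X[at(i, j)] = best; tbX[at(i, j)] = who; }
      }
      // Y: gap in A (consume b_j); free at i == n if terminal_free
      {
        bool term = terminal_free && (i == n);
        double op = term ? 0.0 : gap_open;
        double ex = term ? 0.0 : gap_extend;
        double vm = M[at(i, j - 1)] == NEG_INF ? NEG_INF : M[at(i, j - 1)] - op;
        double vx = X[at(i, j - 1)] == NEG_INF ? NEG_INF : X[at(i, j - 1)] - op;
        double vy = Y[at(i, j - 1)] == NEG_INF ? NEG_INF : Y[at(i, j - 1)] - ex;
        double best = vm; signed char who = 0;
        if (vx > best) { best = vx; who = 1; }
        if (vy > best) { best = vy; who = 2; }
        if (best > NEG_INF) { Y[at(i, j)] = best; tbY[at(i, j)] = who; }
      }
    }
  }

  // final state: prefer M > X > Y on ties
  double vm = M[at(n, m)], vx = X[at(n, m)], vy = Y[at(n, m)];
  double best = vm; int state = 0;
  if (vx > best) { best = vx; state = 1; }
  if (vy > best) { best = vy; state = 2; }

  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = tbM[at(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
    } else if (state == 1) {
      prev = tbX[at(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i;
    } else {
      prev = tbY[at(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j;
    }
    state = prev;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best,
                      _["a_pos"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_pos"] = IntegerVector(bi.begin(), bi.end()));
}
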