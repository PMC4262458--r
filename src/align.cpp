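#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment with free end gaps ("glocal"/overlap mode).
// Sequences arrive as 0-based indices into the substitution matrix, so the
// kernel is alphabet-agnostic.  A gap of length k costs open + k * ext.
//
// Tie-break convention (mirrored by the reference DP used in the test
// suite; changing it silently breaks exact-equality checks):
//   * cell state preference on equal score: M (diagonal) > X (gap in b,
//     consumes a) > Y (gap in a, consumes b);
//   * traceback predecessor preference: same order;
//   * terminal cell: scanned along the last row (j = 0..m) and then the
//     last column (i = 0..n-1); only a strictly greater score replaces
//     the incumbent.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List align_overlap_cpp(IntegerVector a, IntegerVector b,
                       NumericMatrix submat,
                       double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("empty sequence");

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j)
      M(i, j) = X(i, j) = Y(i, j) = NEG_INF;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // H at (i-1, j-1): 0 on the boundary (free leading end gaps)
      double prev;
      if (i == 1 || j == 1) {
        prev = 0.0;
      } else {
        prev = M(i - 1, j - 1);
        if (X(i - 1, j - 1) > prev) prev = X(i - 1, j - 1);
        if (Y(i - 1, j - 1) > prev) prev = Y(i - 1, j - 1);
      }
      M(i, j) = submat(a[i - 1], b[j - 1]) + prev;

      if (i >= 2) {
        double fromM = M(i - 1, j) - gap_open - gap_ext;
        double fromX = X(i - 1, j) - gap_ext;
        X(i, j) = fromM >= fromX ? fromM : fromX;
      }
      if (j >= 2) {
        double fromM = M(i, j - 1) - gap_open - gap_ext;
        double fromY = Y(i, j - 1) - gap_ext;
        Y(i, j) = fromM >= fromY ? fromM : fromY;
      }
    }
  }

  // terminal cell over last row then last column, strict improvement only
  double best = NEG_INF;
  int ti = -1, tj = -1;
  for (int j = 0; j <= m; ++j) {
    double h = (j == 0) ? 0.0 :
      std::max(M(n, j), std::max(X(n, j), Y(n, j)));
    if (h > best) { best = h; ti = n; tj = j; }
  }
  for (int i = 0; i < n; ++i) {
    double h = (i == 0) ? 0.0 :
      std::max(M(i, m), std::max(X(i, m), Y(i, m)));
    if (h > best) { best = h; ti = i; tj = m; }
  }

  int matches = 0, columns = 0;
  int qs = 0, qe = 0, ss = 0, se = 0; // 1-based inclusive aligned spans
  if (ti > 0 && tj > 0 && best > NEG_INF / 2) {
    int i = ti, j = tj;
    // state: 0 = M, 1 = X, 2 = Y
    int state;
    double h = M(i, j); state = 0;
    if (X(i, j) > h) { h = X(i, j); state = 1; }
    if (Y(i, j) > h) { h = Y(i, j); state = 2; }
    qe = i; se = j;
    bool done = false;
    while (!done) {
      if (state == 0) {
        ++columns;
        if (a[i - 1] == b[j - 1]) ++matches;
        qs = i; ss = j;
        if (i == 1 || j == 1) { done = true; }
        else {
          double pm = M(i - 1, j - 1), px = X(i - 1, j - 1),
                 py = Y(i - 1, j - 1);
          state = (pm >= px && pm >= py) ? 0 : (px >= py ? 1 : 2);
          --i; --j;
        }
      } else if (state == 1) {
        ++columns;
        // ties resolved toward M at matrix fill, so equality means fromM
        double fromM = M(i - 1, j) - gap_open - gap_ext;
        state = (std::abs(fromM - X(i, j)) < 1e-9) ? 0 : 1;
        --i;
      } else {
        ++columns;
        double fromM = M(i, j - 1) - gap_open - gap_ext;
        state = (std::abs(fromM - Y(i, j)) < 1e-9) ? 0 : 2;
        --j;
      }
    }
  }

  return List::create(_["score"] = best,
                      _["matches"] = matches,
                      _["columns"] = columns,
                      _["query_span"] = IntegerVector::create(qs, qe),
                      _["subject_span"] = IntegerVector::create(ss, se));
}
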