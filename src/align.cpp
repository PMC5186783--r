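#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels (Gotoh three-state recursion).
//
// Scoring convention: a gap of length L costs gap_open + L * gap_extend
// (so the first gapped residue costs gap_open + gap_extend).  Sequences
// arrive as 1-based integer index vectors into the substitution matrix.
//
// Tie-breaking in tracebacks is fixed so position maps are reproducible:
// diagonal (match state) is preferred over a gap, and a gap in the target
// (consuming a reference residue) over a gap in the reference.

static const int NEG_INF = -1000000000;

inline int smat(const IntegerMatrix &m, int a, int b) {
  return m(a - 1, b - 1);
}

// [[Rcpp::export(name = ".sw_score")]]
int sw_score(IntegerVector a, IntegerVector b, IntegerMatrix sub,
             int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<int> M(m + 1, 0), X(m + 1, NEG_INF), Y(m + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diagM = 0, diagX = NEG_INF, diagY = NEG_INF; // cells (i-1, j-1)
    M[0] = 0; X[0] = NEG_INF; Y[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      int upM = M[j], upX = X[j], upY = Y[j]; // cells (i-1, j)
      int s = smat(sub, a[i - 1], b[j - 1]);
      int x = std::max(upM - gap_open - gap_extend, upX - gap_extend); // gap in b
      int y = std::max(M[j - 1] - gap_open - gap_extend, Y[j - 1] - gap_extend); // gap in a
      int d = std::max(std::max(diagM, diagX), std::max(diagY, 0)) + s;
      M[j] = d; X[j] = x; Y[j] = y;
      int cell = std::max(std::max(d, x), std::max(y, 0));
      if (cell > best) best = cell;
      diagM = upM; diagX = upX; diagY = upY;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".nw_score")]]
int nw_score(IntegerVector a, IntegerVector b, IntegerMatrix sub,
             int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<int> M(m + 1), X(m + 1), Y(m + 1);
  M[0] = 0; X[0] = NEG_INF; Y[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M[j] = NEG_INF; X[j] = NEG_INF;
    Y[j] = -gap_open - j * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    int diagM = M[0], diagX = X[0], diagY = Y[0];
    M[0] = NEG_INF; Y[0] = NEG_INF; X[0] = -gap_open - i * gap_extend;
    for (int j = 1; j <= m; ++j) {
      int upM = M[j], upX = X[j], upY = Y[j];
      int s = smat(sub, a[i - 1], b[j - 1]);
      int x = std::max(upM - gap_open - gap_extend, upX - gap_extend);
      int y = std::max(M[j - 1] - gap_open - gap_extend, Y[j - 1] - gap_extend);
      int d = std::max(std::max(diagM, diagX), diagY) + s;
      M[j] = d; X[j] = x; Y[j] = y;
      diagM = upM; diagX = upX; diagY = upY;
    }
  }
  return std::max(std::max(M[m], X[m]), Y[m]);
}

// Global alignment with full traceback; returns the reference -> target
// position map (0 where the reference residue aligns to a gap).
// a is the reference, b the target. States: 0 = M, 1 = X (gap in target,
// reference consumed), 2 = Y (gap in reference, target consumed).
// [[Rcpp::export(name = ".nw_map")]]
IntegerVector nw_map(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                     int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  IntegerMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -gap_open - j * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -gap_open - i * gap_extend;
    for (int j = 1; j <= m; ++j) {
      int s = smat(sub, a[i - 1], b[j - 1]);
      M(i, j) = std::max(std::max(M(i - 1, j - 1), X(i - 1, j - 1)),
                         Y(i - 1, j - 1)) + s;
      X(i, j) = std::max(M(i - 1, j) - gap_open - gap_extend,
                         X(i - 1, j) - gap_extend);
      Y(i, j) = std::max(M(i, j - 1) - gap_open - gap_extend,
                         Y(i, j - 1) - gap_extend);
    }
  }
  // end state: prefer M, then X (gap in target), then Y
  int state;
  int fin = std::max(std::max(M(n, m), X(n, m)), Y(n, m));
  if (M(n, m) == fin) state = 0; else if (X(n, m) == fin) state = 1; else state = 2;

  IntegerVector map(n);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      map[i - 1] = j;
      int prev = M(i, j) - smat(sub, a[i - 1], b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M(i, j) == prev) state = 0;
      else if (X(i, j) == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      map[i - 1] = 0;
      int cur = X(i, j);
      --i;
      if (M(i, j) - gap_open - gap_extend == cur) state = 0;
      else state = 1;
    } else {
      int cur = Y(i, j);
      --j;
      if (M(i, j) - gap_open - gap_extend == cur) state = 0;
      else state = 2;
    }
  }
  return map;
}

// Local alignment with traceback; returns score plus the aligned segments
// as index ranges and the per-column operation string.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
              int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  IntegerMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  int best = 0, bi = 0, bj = 0;
  for (int j = 0; j <= m; ++j) { M(0, j) = 0; X(0, j) = NEG_INF; Y(0, j) = NEG_INF; }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = 0; X(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      int s = smat(sub, a[i - 1], b[j - 1]);
      int d = std::max(std::max(M(i - 1, j - 1), X(i - 1, j - 1)),
                       std::max(Y(i - 1, j - 1), 0)) + s;
      M(i, j) = d;
      X(i, j) = std::max(M(i - 1, j) - gap_open - gap_extend,
                         X(i - 1, j) - gap_extend);
      Y(i, j) = std::max(M(i, j - 1) - gap_open - gap_extend,
                         Y(i, j - 1) - gap_extend);
      int cell = std::max(std::max(d, X(i, j)), Y(i, j));
      if (cell > best) { best = cell; bi = i; bj = j; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1, _["ops"] = "");
  }
  // traceback from (bi, bj); entry state preference: M, X, Y
  int state;
  if (M(bi, bj) == best) state = 0; else if (X(bi, bj) == best) state = 1; else state = 2;
  std::string ops;
  int i = bi, j = bj;
  bool done = false;
  while (!done) {
    if (state == 0) {
      ops.push_back('M');
      int prev = M(i, j) - smat(sub, a[i - 1], b[j - 1]);
      --i; --j;
      if (prev == 0 || (M(i, j) != prev && X(i, j) != prev && Y(i, j) != prev)) {
        done = true;
      } else if (M(i, j) == prev) state = 0;
      else if (X(i, j) == prev) state = 1;
      else state = 2;
      if (prev == 0) done = true;
    } else if (state == 1) {
      ops.push_back('D'); // gap in b, consumes a
      int cur = X(i, j);
      --i;
      if (M(i, j) - gap_open - gap_extend == cur) state = 0; else state = 1;
    } else {
      ops.push_back('I'); // gap in a, consumes b
      int cur = Y(i, j);
      --j;
      if (M(i, j) - gap_open - gap_extend == cur) state = 0; else state = 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["ops"] = ops);
}

// Batched best-score search: score every query against every target.
// Returns an integer matrix (queries x targets).
// [[Rcpp::export(name = ".sw_score_matrix")]]
IntegerMatrix sw_score_matrix(List queries, List targets, IntegerMatrix sub,
                              int gap_open, int gap_extend) {
  const int nq = queries.size(), nt = targets.size();
  IntegerMatrix out(nq, nt);
  for (int q = 0; q < nq; ++q) {
    IntegerVector qa = queries[q];
    for (int t = 0; t < nt; ++t) {
      IntegerVector tb = targets[t];
      out(q, t) = sw_score(qa, tb, sub, gap_open, gap_extend);
    }
  }
  return out;
}
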