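#include <Rcpp.h>
using namespace Rcpp;

// Banded DTW between two scalar channels.
//
// Local cost d(m, n) = |t[m] - s[n]| (1-indexed in the maths, 0-indexed
// here).  The accumulated-cost programme is
//   C(m, n) = d(m, n) + min{C(m-1, n), C(m, n-1), C(m-1, n-1)}
// restricted to the Sakoe-Chiba band |m - n| <= band.  The reported
// distance is the sum of local costs over the path cells (C(M, N)), so a
// path of length L through identical signals costs 0 and a diagonal path
// through unit costs costs max(M, N).
//
// mode greedy follows the literal local-move rule: from (m, n) advance to
// the admissible neighbour among (m+1, n), (m, n+1), (m+1, n+1) with the
// smallest *local* cost, accumulating local costs until (M, N).
//
// Tie-breaks (both modes, and in backtracking): diagonal, then the
// template-advancing vertical move, then horizontal.  Deterministic paths
// are required for reproducible serialization.

static inline bool in_band(int m, int n, int band) {
  // band < 0 encodes "unbounded"
  return band < 0 || std::abs(m - n) <= band;
}

// [[Rcpp::export]]
List cpp_dtw(NumericVector tmpl, NumericVector seq, int band, bool greedy,
             bool want_path) {
  const int M = tmpl.size(), N = seq.size();
  if (M < 1 || N < 1) stop("empty input");
  if (band >= 0 && band < std::abs(M - N))
    stop("band half-width %d infeasible for lengths %d x %d; minimum is %d",
         band, M, N, std::abs(M - N));

  std::vector<int> px, py;
  double dist = 0.0;

  if (greedy) {
    int m = 0, n = 0;
    dist = std::abs(tmpl[0] - seq[0]);
    px.push_back(1); py.push_back(1);
    while (m < M - 1 || n < N - 1) {
      double best = R_PosInf;
      int bm = -1, bn = -1;
      // preference order: diagonal, vertical (m+1), horizontal (n+1)
      if (m + 1 < M && n + 1 < N && in_band(m + 1, n + 1, band)) {
        best = std::abs(tmpl[m + 1] - seq[n + 1]); bm = m + 1; bn = n + 1;
      }
      if (m + 1 < M && in_band(m + 1, n, band)) {
        double c = std::abs(tmpl[m + 1] - seq[n]);
        if (c < best) { best = c; bm = m + 1; bn = n; }
      }
      if (n + 1 < N && in_band(m, n + 1, band)) {
        double c = std::abs(tmpl[m] - seq[n + 1]);
        if (c < best) { best = c; bm = m; bn = n + 1; }
      }
      m = bm; n = bn;
      dist += best;
      px.push_back(m + 1); py.push_back(n + 1);
    }
  } else {
    NumericMatrix C(M, N);
    std::fill(C.begin(), C.end(), R_PosInf);
    for (int m = 0; m < M; ++m) {
      int lo = (band < 0) ? 0 : std::max(0, m - band);
      int hi = (band < 0) ? N - 1 : std::min(N - 1, m + band);
      for (int n = lo; n <= hi; ++n) {
        double d = std::abs(tmpl[m] - seq[n]);
        if (m == 0 && n == 0) { C(0, 0) = d; continue; }
        double prev = R_PosInf;
        if (m > 0 && n > 0) prev = C(m - 1, n - 1);
        if (m > 0 && C(m - 1, n) < prev) prev = C(m - 1, n);
        if (n > 0 && C(m, n - 1) < prev) prev = C(m, n - 1);
        C(m, n) = d + prev;
      }
    }
    dist = C(M - 1, N - 1);
    if (want_path) {
      int m = M - 1, n = N - 1;
      px.push_back(m + 1); py.push_back(n + 1);
      while (m > 0 || n > 0) {
        double bd = R_PosInf;
        int bm = m, bn = n;
        if (m > 0 && n > 0 && C(m - 1, n - 1) <= bd) {
          bd = C(m - 1, n - 1); bm = m - 1; bn = n - 1;
        }
        if (m > 0 && C(m - 1, n) < bd) { bd = C(m - 1, n); bm = m - 1; bn = n; }
        if (n > 0 && C(m, n - 1) < bd) { bd = C(m, n - 1); bm = m; bn = n - 1; }
        m = bm; n = bn;
        px.push_back(m + 1); py.push_back(n + 1);
      }
      std::reverse(px.begin(), px.end());
      std::reverse(py.begin(), py.end());
    }
  }

  return List::create(_["distance"] = dist,
                      _["ix"] = IntegerVector(px.begin(), px.end()),
                      _["iy"] = IntegerVector(py.begin(), py.end()));
}

// Distance-only DP, used in the batch kernels.
static double dtw_dist_only(const double* t, const double* s, int M, int N,
                            int band) {
  std::vector<double> prev(N, R_PosInf), cur(N, R_PosInf);
  for (int m = 0; m < M; ++m) {
    int lo = (band < 0) ? 0 : std::max(0, m - band);
    int hi = (band < 0) ? N - 1 : std::min(N - 1, m + band);
    std::fill(cur.begin(), cur.end(), R_PosInf);
    for (int n = lo; n <= hi; ++n) {
      double d = std::fabs(t[m] - s[n]);
      if (m == 0 && n == 0) { cur[0] = d; continue; }
      double best = R_PosInf;
      if (m > 0 && n > 0 && prev[n - 1] < best) best = prev[n - 1];
      if (m > 0 && prev[n] < best) best = prev[n];
      if (n > 0 && cur[n - 1] < best) best = cur[n - 1];
      cur[n] = d + best;
    }
    std::swap(prev, cur);
  }
  return prev[N - 1];
}

// Per-channel DTW distances between every query and every template.
// queries:   C x L x nq array, templates: C x L x nt array (same C, L).
// Returns an nq x nt x C array of banded optimal DTW distances.
// [[Rcpp::export]]
NumericVector cpp_channel_distances(NumericVector queries,
                                    NumericVector templates, int band) {
  IntegerVector dq = queries.attr("dim"), dt = templates.attr("dim");
  if (dq.size() != 3 || dt.size() != 3) stop("expected 3-d arrays");
  const int C = dq[0], L = dq[1], nq = dq[2];
  if (dt[0] != C || dt[1] != L)
    stop("query and template arrays disagree in channels or length");
  const int nt = dt[2];
  if (band >= 0 && band < 0) stop("unreachable");

  NumericVector out(static_cast<R_xlen_t>(nq) * nt * C);
  out.attr("dim") = IntegerVector::create(nq, nt, C);
  // Channels are stored as rows; copy each channel into contiguous buffers.
  std::vector<double> qbuf(L), tbuf(L);
  const double* Q = REAL(queries);
  const double* T = REAL(templates);
  double* O = REAL(out);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < nt; ++j) {
      for (int l = 0; l < L; ++l) tbuf[l] = T[c + (R_xlen_t)C * (l + (R_xlen_t)L * j)];
      for (int i = 0; i < nq; ++i) {
        for (int l = 0; l < L; ++l) qbuf[l] = Q[c + (R_xlen_t)C * (l + (R_xlen_t)L * i)];
        double d = dtw_dist_only(tbuf.data(), qbuf.data(), L, L, band);
        O[i + (R_xlen_t)nq * (j + (R_xlen_t)nt * c)] = d;
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return out;
}
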