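#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
//
// a, b: 1-based indices into the scoring-matrix alphabet.
// S: substitution matrix. gap_open/gap_ext: positive penalties; a gap of
// length L costs gap_open + L * gap_ext (BLAST convention).
//
// Traceback is deterministic: the start cell is the first maximal cell in
// row-major order, and at every step diagonal is preferred over up (gap in
// b) over left (gap in a); the path stops at score 0.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  // matrices stored as (n+1) x (m+1), row-major via index i*(m+1)+j
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((n + 1) * (m + 1), NEG); // gap in b, consumes a
  std::vector<double> Iy((n + 1) * (m + 1), NEG); // gap in a, consumes b
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(a[i - 1] - 1, b[j - 1] - 1);
      double prev = std::max(0.0, std::max(M[at(i - 1, j - 1)],
                     std::max(Ix[at(i - 1, j - 1)], Iy[at(i - 1, j - 1)])));
      M[at(i, j)] = std::max(0.0, prev + s);
      Ix[at(i, j)] = std::max(M[at(i - 1, j)] - gap_open - gap_ext,
                              Ix[at(i - 1, j)] - gap_ext);
      Iy[at(i, j)] = std::max(M[at(i, j - 1)] - gap_open - gap_ext,
                              Iy[at(i, j - 1)] - gap_ext);
      if (M[at(i, j)] > best) {
        best = M[at(i, j)];
        bi = i; bj = j;
      }
    }
  }

  std::vector<int> out_a, out_b; // 0 = gap
  int ai_end = 0, bj_end = 0, ai_start = 0, bj_start = 0;
  if (best > 0.0) {
    ai_end = bi; bj_end = bj;
    int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix, 2 = Iy
    while (i > 0 && j > 0) {
      if (state == 0) {
        double s = S(a[i - 1] - 1, b[j - 1] - 1);
        double v = M[at(i, j)] - s;
        out_a.push_back(a[i - 1]);
        out_b.push_back(b[j - 1]);
        --i; --j;
        if (v <= 1e-9) break; // local alignment start
        if (std::abs(M[at(i, j)] - v) < 1e-9) state = 0;
        else if (std::abs(Ix[at(i, j)] - v) < 1e-9) state = 1;
        else state = 2;
      } else if (state == 1) { // gap in b, consumed a[i]
        out_a.push_back(a[i - 1]);
        out_b.push_back(0);
        double v = Ix[at(i, j)];
        if (std::abs(M[at(i - 1, j)] - gap_open - gap_ext - v) < 1e-9) state = 0;
        else state = 1;
        --i;
      } else { // gap in a, consumed b[j]
        out_a.push_back(0);
        out_b.push_back(b[j - 1]);
        double v = Iy[at(i, j)];
        if (std::abs(M[at(i, j - 1)] - gap_open - gap_ext - v) < 1e-9) state = 0;
        else state = 2;
        --j;
      }
    }
    ai_start = i + 1; bj_start = j + 1;
    std::reverse(out_a.begin(), out_a.end());
    std::reverse(out_b.begin(), out_b.end());
  }

  return List::create(
    _["score"] = best,
    _["a_idx"] = IntegerVector(out_a.begin(), out_a.end()),
    _["b_idx"] = IntegerVector(out_b.begin(), out_b.end()),
    _["a_start"] = ai_start, _["a_end"] = ai_end,
    _["b_start"] = bj_start, _["b_end"] = bj_end);
}
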