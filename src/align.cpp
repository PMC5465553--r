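#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gotoh local alignment with affine gaps. Sequences arrive as 1-based
// indices into the substitution matrix. Gap of length L costs
// gap_open + L * gap_ext (first gapped residue pays open + ext), matching
// the gapOpening/gapExtension convention of Biostrings::pairwiseAlignment.
//
// Traceback starts at the highest-scoring cell (ties: smallest row, then
// column) and prefers diagonal, then gap-in-subject (consume query), then
// gap-in-query. Identity is computed over aligned columns with gap columns
// counted as mismatches; coverage is the fraction of the query consumed.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b,
                  IntegerMatrix smat, double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * (m + 1), 0.0),
                      E((n + 1) * (m + 1), NEG),
                      F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[at(i, j - 1)] - (gap_open + gap_ext),
                          E[at(i, j - 1)] - gap_ext);
      double f = std::max(H[at(i - 1, j)] - (gap_open + gap_ext),
                          F[at(i - 1, j)] - gap_ext);
      double s = smat(a[i - 1] - 1, b[j - 1] - 1);
      double h = H[at(i - 1, j - 1)] + s;
      h = std::max(std::max(h, e), std::max(f, 0.0));
      E[at(i, j)] = e; F[at(i, j)] = f; H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int matches = 0, aln_len = 0;
  int a_end = bi, b_end = bj, a_start = bi, b_start = bj;
  if (best > 0) {
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
    while (true) {
      if (state == 0) {
        double h = H[at(i, j)];
        if (h <= 0.0) break;
        double s = smat(a[i - 1] - 1, b[j - 1] - 1);
        if (h == H[at(i - 1, j - 1)] + s) {
          ++aln_len;
          if (a[i - 1] == b[j - 1]) ++matches;
          a_start = i; b_start = j;
          --i; --j;
        } else if (h == F[at(i, j)]) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 2) { // consume a[i], gap in subject
        ++aln_len;
        a_start = i;
        double f = F[at(i, j)];
        bool from_h = (f == H[at(i - 1, j)] - (gap_open + gap_ext));
        --i;
        if (from_h) state = 0;
      } else { // E: consume b[j], gap in query
        ++aln_len;
        b_start = j;
        double e = E[at(i, j)];
        bool from_h = (e == H[at(i, j - 1)] - (gap_open + gap_ext));
        --j;
        if (from_h) state = 0;
      }
    }
  } else {
    a_start = a_end = b_start = b_end = 0;
  }

  double identity = aln_len > 0 ? (double)matches / aln_len : 0.0;
  double coverage = (n > 0 && best > 0)
    ? (double)(a_end - a_start + 1) / n : 0.0;
  return List::create(_["score"] = best, _["identity"] = identity,
                      _["coverage"] = coverage, _["matches"] = matches,
                      _["aln_len"] = aln_len,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}
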