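#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded local alignment (Smith-Waterman, affine gaps) of a germline
// reference segment against a contig. The band is centred on a seed
// diagonal d = query_pos - ref_pos (1-based): for contig position i the
// reference positions j with |(i - j) - diag| <= band are evaluated.
// A gap of length L costs -(gap_open + (L-1) * gap_extend) with the
// default scores (+2 match, -2 mismatch, -5 open, -2 extend).
//
// Returns the best local score, the aligned 1-based ranges on contig and
// reference, and for every reference position inside the aligned range
// the contig position it pairs with (NA where the reference base is
// deleted from the contig). Anchor positions are projected through this
// map on the R side.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_banded")]]
List align_banded(const std::string& query, const std::string& ref,
                  int diag, int band,
                  double match = 2.0, double mismatch = -2.0,
                  double gap_open = -5.0, double gap_extend = -2.0) {
  const int m = (int) query.size();
  const int n = (int) ref.size();
  const int w = 2 * band + 1;

  if (m < 1 || n < 1) stop("empty sequence");

  // offset storage: cell (i, j) lives at column jj = j - (i - diag - band)
  std::vector<double> H((size_t)(m + 1) * w, 0.0);
  std::vector<double> E((size_t)(m + 1) * w, NEG_INF);
  std::vector<double> F((size_t)(m + 1) * w, NEG_INF);
  // traceback: 0 = start (score 0), 1 = diagonal, 2 = from E (gap in
  // query, ref consumed), 3 = from F (gap in ref, query consumed)
  std::vector<unsigned char> TB((size_t)(m + 1) * w, 0);
  std::vector<unsigned char> TE((size_t)(m + 1) * w, 0); // 1: E opened here
  std::vector<unsigned char> TF((size_t)(m + 1) * w, 0);

  auto idx = [&](int i, int jj) { return (size_t) i * w + jj; };

  double best = 0.0;
  int best_i = -1, best_jj = -1;

  for (int i = 1; i <= m; ++i) {
    const int lo = std::max(1, i - diag - band);
    const int hi = std::min(n, i - diag + band);
    for (int j = lo; j <= hi; ++j) {
      const int jj = j - (i - diag - band);

      // E: gap in query (comes from (i, j-1) -> jj - 1 in same row)
      double e = NEG_INF;
      unsigned char te = 0;
      if (jj - 1 >= 0 && j - 1 >= 1) {
        const double open = H[idx(i, jj - 1)] + gap_open;
        const double ext  = E[idx(i, jj - 1)] + gap_extend;
        if (open >= ext) { e = open; te = 1; } else { e = ext; te = 0; }
      }
      E[idx(i, jj)] = e; TE[idx(i, jj)] = te;

      // F: gap in ref (comes from (i-1, j) -> jj + 1 in row above)
      double f = NEG_INF;
      unsigned char tf = 0;
      if (jj + 1 < w) {
        const double open = H[idx(i - 1, jj + 1)] + gap_open;
        const double ext  = F[idx(i - 1, jj + 1)] + gap_extend;
        if (open >= ext) { f = open; tf = 1; } else { f = ext; tf = 0; }
      }
      F[idx(i, jj)] = f; TF[idx(i, jj)] = tf;

      // diagonal (i-1, j-1) -> same jj in row above
      const double s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      const double d = H[idx(i - 1, jj)] + s;

      double h = 0.0; unsigned char tb = 0;
      if (d > h) { h = d; tb = 1; }
      if (e > h) { h = e; tb = 2; }
      if (f > h) { h = f; tb = 3; }
      H[idx(i, jj)] = h; TB[idx(i, jj)] = tb;

      if (h > best) { best = h; best_i = i; best_jj = jj; }
    }
  }

  IntegerVector ref_to_query(n, NA_INTEGER);

  if (best_i < 0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                        _["r_start"] = NA_INTEGER, _["r_end"] = NA_INTEGER,
                        _["ref_to_query"] = ref_to_query);
  }

  // traceback from the best cell
  int i = best_i, jj = best_jj;
  int j = jj + (i - diag - band);
  const int q_end = i, r_end = j;
  int q_start = i, r_start = j;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F

  while (true) {
    if (state == 0) {
      const unsigned char tb = TB[idx(i, jj)];
      if (tb == 0) break;
      if (tb == 1) {
        ref_to_query[j - 1] = i;
        q_start = i; r_start = j;
        --i; --j; // jj unchanged under simultaneous step
      } else if (tb == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: ref j consumed by a gap in the query
      const unsigned char te = TE[idx(i, jj)];
      r_start = j;
      --j; --jj;
      if (te == 1) state = 0;
    } else {               // F: query i consumed by a gap in the ref
      const unsigned char tf = TF[idx(i, jj)];
      q_start = i;
      --i; ++jj;
      if (tf == 1) state = 0;
    }
    if (i < 0 || j < 0) break;
  }

  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["r_start"] = r_start, _["r_end"] = r_end,
                      _["ref_to_query"] = ref_to_query);
}
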