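// Affine-gap pairwise nucleotide alignment (Gotoh three-state DP).
//
// Score convention: match > 0 > mismatch; a gap run of length L costs
// gap_open + (L - 1) * gap_extend, both negative, gap_open <= gap_extend.
// Symbols are compared literally: IUPAC-compatible but non-identical
// symbols score as mismatches, matching the percent-identity convention.
//
// Traceback is deterministic: at every choice the diagonal (match state)
// is preferred, then the vertical gap (residue of A over '-'), then the
// horizontal gap.

#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes
enum { SM = 0, SX = 1, SY = 2, SSTART = 3 };

struct AlnResult {
  std::string a, b;
  double score;
};

static void align_core(const std::string& a, const std::string& b,
                       bool local, double match, double mismatch,
                       double gopen, double gext, AlnResult& out) {
  const int n = a.size(), m = b.size();
  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG_INF), X((n + 1) * w, NEG_INF),
      Y((n + 1) * w, NEG_INF);
  std::vector<unsigned char> tM((n + 1) * w, SSTART), tX((n + 1) * w, SSTART),
      tY((n + 1) * w, SSTART);

  M[0] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[i * w] = gopen + (i - 1) * gext;
      tX[i * w] = (i == 1) ? SM : SX;
    }
    for (int j = 1; j <= m; ++j) {
      Y[j] = gopen + (j - 1) * gext;
      tY[j] = (j == 1) ? SM : SY;
    }
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * w + j, d = (i - 1) * w + (j - 1), u = (i - 1) * w + j,
                l = i * w + (j - 1);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;

      // M: from any state at (i-1, j-1); tie priority M > X > Y
      double vm = M[d], vx = X[d], vy = Y[d];
      double pv = vm;
      unsigned char pt = SM;
      if (vx > pv) { pv = vx; pt = SX; }
      if (vy > pv) { pv = vy; pt = SY; }
      double mval = (pv == NEG_INF) ? NEG_INF : pv + s;
      unsigned char mtb = pt;
      if (local) {
        if (mval < s) { mval = s; mtb = SSTART; }  // start fresh at (i, j)
        if (mval < 0) mval = NEG_INF;              // never extend negative
      }
      M[c] = mval;
      tM[c] = mtb;

      // X: gap in B (consume a[i-1]); from (i-1, j)
      {
        double om = (M[u] == NEG_INF) ? NEG_INF : M[u] + gopen;
        double ox = (X[u] == NEG_INF) ? NEG_INF : X[u] + gext;
        double oy = (Y[u] == NEG_INF) ? NEG_INF : Y[u] + gopen;
        double v = om;
        unsigned char t = SM;
        if (ox > v) { v = ox; t = SX; }
        if (oy > v) { v = oy; t = SY; }
        X[c] = v;
        tX[c] = t;
      }
      // Y: gap in A (consume b[j-1]); from (i, j-1)
      {
        double om = (M[l] == NEG_INF) ? NEG_INF : M[l] + gopen;
        double oy = (Y[l] == NEG_INF) ? NEG_INF : Y[l] + gext;
        double ox = (X[l] == NEG_INF) ? NEG_INF : X[l] + gopen;
        double v = om;
        unsigned char t = SM;
        if (oy > v) { v = oy; t = SY; }
        if (ox > v) { v = ox; t = SX; }
        Y[c] = v;
        tY[c] = t;
      }

      if (local && M[c] != NEG_INF && M[c] > best) {
        best = M[c];
        best_i = i;
        best_j = j;
      }
    }
  }

  std::string ra, rb;
  if (local) {
    out.score = best;
    if (best_i == 0) {  // empty optimal local alignment
      out.a.clear();
      out.b.clear();
      return;
    }
    int i = best_i, j = best_j;
    unsigned char st = SM;
    while (true) {
      const int c = i * w + j;
      if (st == SM) {
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        unsigned char nx = tM[c];
        --i;
        --j;
        if (nx == SSTART) break;
        st = nx;
      } else if (st == SX) {
        ra.push_back(a[i - 1]);
        rb.push_back('-');
        st = tX[c];
        --i;
      } else {
        ra.push_back('-');
        rb.push_back(b[j - 1]);
        st = tY[c];
        --j;
      }
    }
  } else {
    const int c = n * w + m;
    double v = M[c];
    unsigned char st = SM;
    if (X[c] > v) { v = X[c]; st = SX; }
    if (Y[c] > v) { v = Y[c]; st = SY; }
    out.score = v;
    int i = n, j = m;
    while (i > 0 || j > 0) {
      const int cc = i * w + j;
      if (st == SM) {
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        st = tM[cc];
        --i;
        --j;
      } else if (st == SX) {
        ra.push_back(a[i - 1]);
        rb.push_back('-');
        st = tX[cc];
        --i;
      } else {
        ra.push_back('-');
        rb.push_back(b[j - 1]);
        st = tY[cc];
        --j;
      }
    }
  }
  out.a.assign(ra.rbegin(), ra.rend());
  out.b.assign(rb.rbegin(), rb.rend());
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, bool local, double match,
               double mismatch, double gap_open, double gap_extend) {
  AlnResult res;
  align_core(a, b, local, match, mismatch, gap_open, gap_extend, res);
  return List::create(_["aligned_a"] = res.a, _["aligned_b"] = res.b,
                      _["score"] = res.score);
}

// Batch alignment statistics for library search: per reference, the
// alignment score, number of identical columns and total columns.
// [[Rcpp::export]]
DataFrame cpp_search_stats(std::string query, CharacterVector refs,
                           LogicalVector local_mode, double match,
                           double mismatch, double gap_open,
                           double gap_extend) {
  const int nref = refs.size();
  NumericVector score(nref);
  IntegerVector nident(nref), ncols(nref);
  AlnResult res;
  for (int r = 0; r < nref; ++r) {
    const std::string ref = as<std::string>(refs[r]);
    align_core(query, ref, local_mode[r], match, mismatch, gap_open,
               gap_extend, res);
    score[r] = res.score;
    int id = 0;
    for (size_t k = 0; k < res.a.size(); ++k) {
      if (res.a[k] == res.b[k] && res.a[k] != '-') ++id;
    }
    nident[r] = id;
    ncols[r] = res.a.size();
  }
  return DataFrame::create(_["score"] = score, _["n_ident"] = nident,
                           _["n_cols"] = ncols);
}
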