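#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <limits>
using namespace Rcpp;

// Semi-global affine-gap alignment: the query is aligned globally, the
// reference contributes free end gaps (leading/trailing reference bases are
// skipped without penalty).  A gap of length L scores gap_open + L * gap_extend.
// States: 0 = M (query base against reference base), 1 = X (gap in the
// reference, query base consumed), 2 = Y (gap in the query, reference base
// consumed).  Ties prefer M, then X, then Y; the end column prefers the
// smallest reference offset.

static const double NEG = -std::numeric_limits<double>::infinity();

static inline double subst_score(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

struct DP {
  int n, m;
  std::vector<double> M, X, Y;
  std::vector<signed char> pM, pX, pY; // predecessor state
  DP(int n_, int m_) : n(n_), m(m_),
    M((n_ + 1) * (m_ + 1), NEG), X((n_ + 1) * (m_ + 1), NEG),
    Y((n_ + 1) * (m_ + 1), NEG),
    pM((n_ + 1) * (m_ + 1), -1), pX((n_ + 1) * (m_ + 1), -1),
    pY((n_ + 1) * (m_ + 1), -1) {}
  inline int at(int i, int j) const { return i * (m + 1) + j; }
};

static void fill_dp(DP &dp, const char *q, const char *r,
                    double match, double mismatch,
                    double gopen, double gext) {
  const int n = dp.n, m = dp.m;
  for (int j = 0; j <= m; ++j) dp.M[dp.at(0, j)] = 0.0; // free leading reference
  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      const int ij = dp.at(i, j);
      if (j >= 1) {
        const int pd = dp.at(i - 1, j - 1);
        double best = dp.M[pd]; signed char ps = 0;
        if (dp.X[pd] > best) { best = dp.X[pd]; ps = 1; }
        if (dp.Y[pd] > best) { best = dp.Y[pd]; ps = 2; }
        if (best > NEG) {
          dp.M[ij] = best + subst_score(q[i - 1], r[j - 1], match, mismatch);
          dp.pM[ij] = ps;
        }
      }
      { // X: consume query base i against a gap
        const int pu = dp.at(i - 1, j);
        double cand = dp.M[pu] + gopen; signed char ps = 0;
        if (dp.X[pu] > cand) { cand = dp.X[pu]; ps = 1; }
        if (dp.Y[pu] + gopen > cand) { cand = dp.Y[pu] + gopen; ps = 2; }
        if (cand > NEG) { dp.X[ij] = cand + gext; dp.pX[ij] = ps; }
      }
      if (j >= 1 && i >= 1) { // Y: consume reference base j against a gap
        const int pl = dp.at(i, j - 1);
        double cand = dp.M[pl] + gopen; signed char ps = 0;
        if (dp.X[pl] + gopen > cand) { cand = dp.X[pl] + gopen; ps = 1; }
        if (dp.Y[pl] > cand) { cand = dp.Y[pl]; ps = 2; }
        if (cand > NEG) { dp.Y[ij] = cand + gext; dp.pY[ij] = ps; }
      }
    }
  }
}

// [[Rcpp::export(name = ".semiglobal_align_cpp")]]
List semiglobal_align_cpp(std::string query, std::string reference,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
  const int n = (int) query.size(), m = (int) reference.size();
  DP dp(n, m);
  fill_dp(dp, query.c_str(), reference.c_str(), match, mismatch,
          gap_open, gap_extend);

  // end: query fully consumed, smallest reference offset on ties, M > X > Y
  double best = NEG; int bj = 0; signed char bs = 0;
  for (int j = 0; j <= m; ++j) {
    const int ij = dp.at(n, j);
    const double sc[3] = { dp.M[ij], dp.X[ij], dp.Y[ij] };
    for (int s = 0; s < 3; ++s) {
      if (sc[s] > best) { best = sc[s]; bj = j; bs = (signed char) s; }
    }
  }

  // traceback
  std::string ops;
  int i = n, j = bj; signed char s = bs;
  int matches = 0;
  while (i > 0) {
    const int ij = dp.at(i, j);
    if (s == 0) {
      char c = (subst_score(query[i - 1], reference[j - 1], 1.0, 0.0) == 1.0)
                 ? 'M' : 'X';
      if (c == 'M') ++matches;
      ops.push_back(c);
      s = dp.pM[ij]; --i; --j;
    } else if (s == 1) {
      ops.push_back('I');
      s = dp.pX[ij]; --i;
    } else {
      ops.push_back('D');
      s = dp.pY[ij]; --j;
    }
  }
  // trailing (in traceback order) Y columns before the query starts would be
  // paid leading gaps; the DP never takes them (M[0][j] = 0 dominates).
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::vector<std::string> op_chr; std::vector<int> op_len;
  for (size_t k = 0; k < ops.size(); ) {
    size_t e = k;
    while (e < ops.size() && ops[e] == ops[k]) ++e;
    op_chr.push_back(std::string(1, ops[k]));
    op_len.push_back((int) (e - k));
    k = e;
  }

  return List::create(
    _["score"] = best,
    _["ref_start"] = j,        // 0-based, half-open [ref_start, ref_end)
    _["ref_end"] = bj,
    _["matches"] = matches,
    _["columns"] = (int) ops.size(),
    _["op"] = op_chr,
    _["len"] = op_len);
}

// [[Rcpp::export(name = ".semiglobal_scores_cpp")]]
NumericVector semiglobal_scores_cpp(CharacterVector queries,
                                    CharacterVector references,
                                    double match, double mismatch,
                                    double gap_open, double gap_extend) {
  const int np = queries.size();
  if (references.size() != np) stop("queries and references differ in length");
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    std::string q = as<std::string>(queries[p]);
    std::string r = as<std::string>(references[p]);
    const int n = (int) q.size(), m = (int) r.size();
    // rolling score-only DP (three rows per state)
    std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG), Yp(m + 1, NEG);
    std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
    for (int i = 1; i <= n; ++i) {
      for (int j = 0; j <= m; ++j) {
        Mc[j] = NEG; Xc[j] = NEG; Yc[j] = NEG;
        if (j >= 1) {
          double b = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
          if (b > NEG)
            Mc[j] = b + subst_score(q[i - 1], r[j - 1], match, mismatch);
        }
        {
          double c = std::max(Mp[j] + gap_open,
                              std::max(Xp[j], Yp[j] + gap_open));
          if (c > NEG) Xc[j] = c + gap_extend;
        }
        if (j >= 1) {
          double c = std::max(Mc[j - 1] + gap_open,
                              std::max(Yc[j - 1], Xc[j - 1] + gap_open));
          if (c > NEG) Yc[j] = c + gap_extend;
        }
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    double best = NEG;
    for (int j = 0; j <= m; ++j)
      best = std::max(best, std::max(Mp[j], std::max(Xp[j], Yp[j])));
    out[p] = best;
  }
  return out;
}
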