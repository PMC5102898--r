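#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Sequences arrive as 1-based integer
// codes into the substitution matrix. A gap of length k scores
// gap_open + k * gap_extend (both <= 0), i.e. the first gapped residue costs
// gap_open + gap_extend.
//
// State matrices: H = best overall, F = ending with a gap in b (consumes a,
// "up"), E = ending with a gap in a (consumes b, "left").

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".gotoh_score")]]
double gotoh_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double gap_open, double gap_extend, bool local) {
  const int m = a.size(), n = b.size();
  const int nres = sub.nrow();
  // flat copy of the substitution matrix and 0-based codes: the Rcpp
  // accessors are far too slow for the inner loop
  std::vector<double> S(sub.begin(), sub.end());
  std::vector<int> ac(m), bc(n);
  for (int i = 0; i < m; ++i) ac[i] = a[i] - 1;
  for (int j = 0; j < n; ++j) bc[j] = b[j] - 1;

  std::vector<double> H(n + 1), E(n + 1), Hprev(n + 1);
  std::vector<double> F(n + 1), Fprev(n + 1);
  const double go = gap_open, ge = gap_extend, gog = go + ge;
  double best = 0.0;

  for (int j = 0; j <= n; ++j) {
    Hprev[j] = local ? 0.0 : (j == 0 ? 0.0 : go + j * ge);
    Fprev[j] = NEG_INF;
  }
  for (int i = 1; i <= m; ++i) {
    H[0] = local ? 0.0 : go + i * ge;
    double e = NEG_INF;
    const double *srow = S.data() + (size_t)ac[i - 1];
    double hprev_jm1 = Hprev[0];
    double h_jm1 = H[0];
    for (int j = 1; j <= n; ++j) {
      double f = std::max(Hprev[j] + gog, Fprev[j] + ge);
      e = std::max(h_jm1 + gog, e + ge);
      double d = hprev_jm1 + srow[(size_t)bc[j - 1] * nres];
      double h = d > f ? d : f;
      if (e > h) h = e;
      if (local && h < 0.0) h = 0.0;
      hprev_jm1 = Hprev[j];
      H[j] = h; F[j] = f;
      h_jm1 = h;
      if (local && h > best) best = h;
    }
    std::swap(H, Hprev); std::swap(F, Fprev);
  }
  return local ? best : Hprev[n];
}

// Full alignment with traceback. Tie-break order at every decision:
// diagonal > up (gap in b) > left (gap in a); gap runs close as early as
// possible, which matches the same preference. For local mode the traceback
// starts at the highest-scoring cell (lowest i, then lowest j on ties) and
// stops at the first zero cell.
// Returns list(score, ops, a_start, a_end, b_start, b_end) where ops is the
// alignment path from start to end: 0 = diagonal, 1 = up, 2 = left, and the
// spans are 1-based inclusive coordinates of the aligned subsequences
// (full sequences in global mode).
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_extend, bool local) {
  const int m = a.size(), n = b.size();
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);

  for (int j = 0; j <= n; ++j) {
    H(0, j) = local ? 0.0 : (j == 0 ? 0.0 : gap_open + j * gap_extend);
    E(0, j) = (j == 0 || local) ? NEG_INF : gap_open + j * gap_extend;
    F(0, j) = NEG_INF;
  }
  for (int i = 1; i <= m; ++i) {
    H(i, 0) = local ? 0.0 : gap_open + i * gap_extend;
    F(i, 0) = local ? NEG_INF : gap_open + i * gap_extend;
    E(i, 0) = NEG_INF;
  }

  int bi = m, bj = n;
  double best = local ? 0.0 : NEG_INF;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double f = std::max(H(i - 1, j) + gap_open + gap_extend, F(i - 1, j) + gap_extend);
      double e = std::max(H(i, j - 1) + gap_open + gap_extend, E(i, j - 1) + gap_extend);
      double d = H(i - 1, j - 1) + sub(a[i - 1] - 1, b[j - 1] - 1);
      double h = std::max(d, std::max(f, e));
      if (local) h = std::max(h, 0.0);
      H(i, j) = h; E(i, j) = e; F(i, j) = f;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  double score;
  if (local) {
    score = best;
    if (best <= 0.0) { bi = 0; bj = 0; }   // empty local alignment
  } else {
    score = H(m, n);
  }

  std::vector<int> ops;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
  while (true) {
    if (local && state == 0 && H(i, j) == 0.0) break;
    if (!local && i == 0 && j == 0) break;
    if (state == 0) {
      if (i > 0 && j > 0 &&
          H(i, j) == H(i - 1, j - 1) + sub(a[i - 1] - 1, b[j - 1] - 1)) {
        ops.push_back(0); --i; --j;
      } else if (i > 0 && H(i, j) == F(i, j)) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ops.push_back(1);
      // prefer closing the gap run (back to H) as soon as it is optimal
      if (H(i - 1, j) + gap_open + gap_extend == F(i, j)) state = 0;
      --i;
    } else {
      ops.push_back(2);
      if (H(i, j - 1) + gap_open + gap_extend == E(i, j)) state = 0;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj);
}
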