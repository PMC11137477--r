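#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Global affine-gap pairwise alignment (Needleman-Wunsch / Gotoh).
//
// A gap run of length L costs gap_open + L * gap_extend (the convention used
// by Biostrings::pairwiseAlignment and by the SIMD alignment libraries this
// mirrors). Symbols absent from `alphabet` are scored with the worst value in
// the substitution matrix.
//
// Traceback tie-break is fixed so that outputs are bit-reproducible:
// diagonal (match/mismatch) is preferred over a gap in b (consuming a),
// which is preferred over a gap in a (consuming b); within each gap state
// the predecessor preference is M, then the same gap state, then the other.

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  IntegerMatrix sub, CharacterVector alphabet,
                  int gap_open, int gap_extend) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  if (n == 0 && m == 0) stop("both sequences are empty");

  int idx[256];
  std::fill(idx, idx + 256, -1);
  for (int i = 0; i < alphabet.size(); ++i) {
    std::string s = as<std::string>(alphabet[i]);
    if (!s.empty()) idx[(unsigned char) s[0]] = i;
  }
  int worst = INT_MAX;
  for (int i = 0; i < sub.nrow(); ++i)
    for (int j = 0; j < sub.ncol(); ++j)
      if (sub(i, j) < worst) worst = sub(i, j);

  const int go = gap_open, ge = gap_extend;
  const size_t W = (size_t) m + 1;

  // state matrices: M = diagonal, X = gap in b (consumes a), Y = gap in a
  std::vector<int> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback pointers: predecessor state 0=M,1=X,2=Y (3 = none/origin)
  std::vector<unsigned char> pM((n + 1) * W, 3), pX((n + 1) * W, 3),
      pY((n + 1) * W, 3);

  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(go + i * ge);
    pX[i * W] = (unsigned char) (i == 1 ? 0 : 1);
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(go + j * ge);
    pY[j] = (unsigned char) (j == 1 ? 0 : 2);
  }

  for (int i = 1; i <= n; ++i) {
    const int ai = idx[(unsigned char) a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int bj = idx[(unsigned char) b[j - 1]];
      int s = (ai < 0 || bj < 0) ? worst : sub(ai, bj);

      // M: preference M > X > Y at ties
      {
        size_t d = (size_t) (i - 1) * W + (j - 1);
        int best = M[d]; unsigned char p = 0;
        if (X[d] > best) { best = X[d]; p = 1; }
        if (Y[d] > best) { best = Y[d]; p = 2; }
        size_t c = (size_t) i * W + j;
        if (best > NEG_INF) { M[c] = best + s; pM[c] = p; }
      }
      // X: gap in b, consumes a[i-1]; open from M or Y, extend from X
      {
        size_t u = (size_t) (i - 1) * W + j;
        int fromM = (M[u] > NEG_INF) ? M[u] - (go + ge) : NEG_INF;
        int fromX = (X[u] > NEG_INF) ? X[u] - ge : NEG_INF;
        int fromY = (Y[u] > NEG_INF) ? Y[u] - (go + ge) : NEG_INF;
        int best = fromM; unsigned char p = 0;
        if (fromX > best) { best = fromX; p = 1; }
        if (fromY > best) { best = fromY; p = 2; }
        size_t c = (size_t) i * W + j;
        if (best > NEG_INF) { X[c] = best; pX[c] = p; }
      }
      // Y: gap in a, consumes b[j-1]
      {
        size_t l = (size_t) i * W + (j - 1);
        int fromM = (M[l] > NEG_INF) ? M[l] - (go + ge) : NEG_INF;
        int fromX = (X[l] > NEG_INF) ? X[l] - (go + ge) : NEG_INF;
        int fromY = (Y[l] > NEG_INF) ? Y[l] - ge : NEG_INF;
        int best = fromM; unsigned char p = 0;
        if (fromX > best) { best = fromX; p = 1; }
        if (fromY > best) { best = fromY; p = 2; }
        size_t c = (size_t) i * W + j;
        if (best > NEG_INF) { Y[c] = best; pY[c] = p; }
      }
    }
  }

  size_t end = (size_t) n * W + m;
  int state = 0, score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = (size_t) i * W + j;
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = pM[c]; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = pX[c]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = pY[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] != '-' && ra[k] == rb[k]) ++matches;

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score, _["matches"] = matches,
                      _["columns"] = (int) ra.size());
}
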