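// Exact affine-gap Smith-Waterman (Gotoh) with full traceback.
// A gap of length L costs gap_open + L * gap_extend, matching the common
// BLAST/Biostrings parameterisation.
#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// [[Rcpp::export]]
SEXP cpp_smith_waterman(std::string a, std::string b, NumericMatrix mat,
                        CharacterVector mat_letters, int gap_open, int gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  if ((double)(m + 1) * (double)(n + 1) > 6e7)
    stop("sequences too long for exact Smith-Waterman traceback");
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < mat_letters.size(); ++i) {
    std::string s = as<std::string>(mat_letters[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  for (int i = 0; i < m; ++i)
    if (lut[(unsigned char)a[i]] < 0) stop("character '%s' not in substitution matrix", std::string(1, a[i]).c_str());
  for (int j = 0; j < n; ++j)
    if (lut[(unsigned char)b[j]] < 0) stop("character '%s' not in substitution matrix", std::string(1, b[j]).c_str());

  const int NEG = -1000000000;
  const int go = gap_open + gap_extend, ge = gap_extend;
  const size_t W = (size_t)(n + 1);
  std::vector<int> H((size_t)(m + 1) * W, 0), E((size_t)(m + 1) * W, NEG),
                   F((size_t)(m + 1) * W, NEG);
  // traceback codes for H: 0 stop, 1 diag, 2 from E (gap in a), 3 from F (gap in b)
  std::vector<signed char> TH((size_t)(m + 1) * W, 0), TE((size_t)(m + 1) * W, 0),
                           TF((size_t)(m + 1) * W, 0); // E/F: 1 = opened from H, 0 = extended
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ai = lut[(unsigned char)a[i - 1]];
    for (int j = 1; j <= n; ++j) {
      const size_t k = (size_t)i * W + j, kl = k - 1, ku = k - W, kd = k - W - 1;
      int e_open = H[kl] - go, e_ext = E[kl] - ge;
      E[k] = e_open >= e_ext ? e_open : e_ext;
      TE[k] = e_open >= e_ext ? 1 : 0;
      int f_open = H[ku] - go, f_ext = F[ku] - ge;
      F[k] = f_open >= f_ext ? f_open : f_ext;
      TF[k] = f_open >= f_ext ? 1 : 0;
      int diag = H[kd] + (int)mat(ai, lut[(unsigned char)b[j - 1]]);
      int h = 0; signed char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[k] > h) { h = E[k]; t = 2; }
      if (F[k] > h) { h = F[k]; t = 3; }
      H[k] = h; TH[k] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return R_NilValue;
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (true) {
    const size_t k = (size_t)i * W + j;
    if (state == 0) {
      signed char t = TH[k];
      if (t == 0) break;
      if (t == 1) {
        ++columns;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      signed char t = TE[k];
      ++columns; --j;
      if (t == 1) state = 0;
    } else {
      signed char t = TF[k];
      ++columns; --i;
      if (t == 1) state = 0;
    }
  }
  return List::create(
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = bi,   // 0-based half-open after R-side use
    _["s_start"] = j, _["s_end"] = bj,
    _["matches"] = matches, _["aln_len"] = columns,
    _["identity_pct"] = 100.0 * (double)matches / (double)columns);
}
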