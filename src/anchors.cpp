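// Seed-chain-extend detector kernels for organelle-derived insertions.
// Coordinates are 0-based half-open on the forward strand throughout; a
// strand '-' anchor at (n, o) means nuclear[n, n+w) equals the reverse
// complement of organelle[o, o+w).
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

static inline char compbase(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

// ---- anchor finding -------------------------------------------------------

// Rolling 2-bit path for w <= 31; string-keyed path otherwise (covers the
// field-standard word size of 50).
// [[Rcpp::export]]
DataFrame cpp_find_anchors(std::string nuc, std::string org, int w) {
  std::vector<int> an, ao;
  std::vector<int> astrand; // +1 / -1
  const int nn = (int)nuc.size(), no = (int)org.size();
  if (w > nn || w > no) {
    return DataFrame::create(_["n_pos"] = IntegerVector(0),
                             _["o_pos"] = IntegerVector(0),
                             _["strand"] = IntegerVector(0));
  }
  if (w <= 31) {
    const uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1ULL);
    std::unordered_map<uint64_t, std::vector<int> > idx;
    idx.reserve((size_t)no * 2);
    // index organelle forward words
    uint64_t code = 0; int valid = 0;
    for (int i = 0; i < no; ++i) {
      int b = base2bit(org[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= w) idx[code].push_back(i - w + 1);
    }
    // scan nuclear; forward and reverse-complement lookups
    uint64_t fc = 0, rc = 0; int v = 0;
    const int shift = 2 * (w - 1);
    for (int i = 0; i < nn; ++i) {
      int b = base2bit(nuc[i]);
      if (b < 0) { v = 0; fc = 0; rc = 0; continue; }
      fc = ((fc << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - b)) << shift);
      if (++v < w) continue;
      int npos = i - w + 1;
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = idx.find(fc);
      if (it != idx.end())
        for (size_t k = 0; k < it->second.size(); ++k) {
          an.push_back(npos); ao.push_back(it->second[k]); astrand.push_back(1);
        }
      it = idx.find(rc);
      if (it != idx.end())
        for (size_t k = 0; k < it->second.size(); ++k) {
          an.push_back(npos); ao.push_back(it->second[k]); astrand.push_back(-1);
        }
    }
  } else {
    std::unordered_map<std::string, std::vector<int> > idx;
    idx.reserve((size_t)no * 2);
    std::vector<int> bad(no + 1, 0); // prefix count of non-ACGT in org
    for (int i = 0; i < no; ++i) bad[i + 1] = bad[i] + (base2bit(org[i]) < 0 ? 1 : 0);
    for (int i = 0; i + w <= no; ++i)
      if (bad[i + w] - bad[i] == 0) idx[org.substr(i, w)].push_back(i);
    std::vector<int> nbad(nn + 1, 0);
    for (int i = 0; i < nn; ++i) nbad[i + 1] = nbad[i] + (base2bit(nuc[i]) < 0 ? 1 : 0);
    std::string word(w, 'A'), rcw(w, 'A');
    for (int i = 0; i + w <= nn; ++i) {
      if (nbad[i + w] - nbad[i] != 0) continue;
      word.assign(nuc, i, w);
      std::unordered_map<std::string, std::vector<int> >::const_iterator it = idx.find(word);
      if (it != idx.end())
        for (size_t k = 0; k < it->second.size(); ++k) {
          an.push_back(i); ao.push_back(it->second[k]); astrand.push_back(1);
        }
      for (int j = 0; j < w; ++j) rcw[j] = compbase(word[w - 1 - j]);
      it = idx.find(rcw);
      if (it != idx.end())
        for (size_t k = 0; k < it->second.size(); ++k) {
          an.push_back(i); ao.push_back(it->second[k]); astrand.push_back(-1);
        }
    }
  }
  return DataFrame::create(_["n_pos"] = wrap(an), _["o_pos"] = wrap(ao),
                           _["strand"] = wrap(astrand));
}

// ---- chaining, merging, extension, banded alignment -----------------------

struct Chain {
  int n_start, n_end, o_start, o_end; // half-open spans
  int last_n, last_o;                 // last anchor start positions
  int count;
  int strand;                         // +1 / -1
};

static bool span_mergeable(const Chain &a, const Chain &b, int G) {
  // a precedes b in nuclear order (a.n_start <= b.n_start). Merge only a
  // true colinear continuation (b extends a on both coordinates within the
  // gap budget) or a fragment contained in a on both coordinates; anything
  // else (e.g. a spurious anchor inside a's nuclear span pointing just past
  // its organelle end) must stay separate or it corrupts the aligned span.
  if (a.strand != b.strand) return false;
  if (b.n_start - a.n_end > G) return false;
  const bool n_contained = b.n_start >= a.n_start && b.n_end <= a.n_end;
  if (a.strand > 0) {
    const bool o_contained = b.o_start >= a.o_start && b.o_end <= a.o_end;
    if (n_contained && o_contained) return true;
    return b.o_start >= a.o_start && b.o_start - a.o_end <= G &&
           b.n_end > a.n_end && b.o_end > a.o_end;
  } else {
    const bool o_contained = b.o_start >= a.o_start && b.o_end <= a.o_end;
    if (n_contained && o_contained) return true;
    return b.o_end <= a.o_end && a.o_start - b.o_end <= G &&
           b.n_end > a.n_end && b.o_start < a.o_start;
  }
}

static void merge_into(Chain &a, const Chain &b) {
  a.n_start = std::min(a.n_start, b.n_start);
  a.n_end   = std::max(a.n_end, b.n_end);
  a.o_start = std::min(a.o_start, b.o_start);
  a.o_end   = std::max(a.o_end, b.o_end);
  a.count  += b.count;
}

static void merge_pass(std::vector<Chain> &chains, int G) {
  bool changed = true;
  while (changed) {
    changed = false;
    std::sort(chains.begin(), chains.end(), [](const Chain &x, const Chain &y) {
      if (x.n_start != y.n_start) return x.n_start < y.n_start;
      return x.o_start < y.o_start;
    });
    std::vector<Chain> out;
    for (size_t i = 0; i < chains.size(); ++i) {
      bool merged = false;
      for (size_t j = 0; j < out.size(); ++j) {
        if (span_mergeable(out[j], chains[i], G)) {
          merge_into(out[j], chains[i]);
          merged = true; changed = true; break;
        }
      }
      if (!merged) out.push_back(chains[i]);
    }
    chains.swap(out);
  }
}

// Ungapped X-drop extension of a chain span along its boundary diagonals.
static void xdrop_extend(Chain &c, const std::string &nuc, const std::string &org,
                         int xdrop) {
  const int nn = (int)nuc.size(), no = (int)org.size();
  if (c.strand > 0) {
    int score = 0, best = 0, besti = 0;
    for (int t = 1; c.n_start - t >= 0 && c.o_start - t >= 0; ++t) {
      char a = nuc[c.n_start - t], b = org[c.o_start - t];
      score += (a == b && base2bit(a) >= 0) ? 1 : -1;
      if (score > best) { best = score; besti = t; }
      if (score < best - xdrop) break;
    }
    c.n_start -= besti; c.o_start -= besti;
    score = 0; best = 0; besti = 0;
    for (int t = 0; c.n_end + t < nn && c.o_end + t < no; ++t) {
      char a = nuc[c.n_end + t], b = org[c.o_end + t];
      score += (a == b && base2bit(a) >= 0) ? 1 : -1;
      if (score > best) { best = score; besti = t + 1; }
      if (score < best - xdrop) break;
    }
    c.n_end += besti; c.o_end += besti;
  } else {
    // nuclear left end pairs with organelle right end
    int score = 0, best = 0, besti = 0;
    for (int t = 1; c.n_start - t >= 0 && c.o_end + t - 1 < no; ++t) {
      char a = nuc[c.n_start - t], b = compbase(org[c.o_end + t - 1]);
      score += (a == b && base2bit(a) >= 0) ? 1 : -1;
      if (score > best) { best = score; besti = t; }
      if (score < best - xdrop) break;
    }
    c.n_start -= besti; c.o_end += besti;
    score = 0; best = 0; besti = 0;
    for (int t = 0; c.n_end + t < nn && c.o_start - t - 1 >= 0; ++t) {
      char a = nuc[c.n_end + t], b = compbase(org[c.o_start - t - 1]);
      score += (a == b && base2bit(a) >= 0) ? 1 : -1;
      if (score > best) { best = score; besti = t + 1; }
      if (score < best - xdrop) break;
    }
    c.n_end += besti; c.o_start -= besti;
  }
}

// Banded global alignment; match +1, mismatch -1, gap -2 per column.
// The reported segment is the maximal-scoring contiguous stretch of the
// global alignment path (Kadane over per-column scores), which trims poorly
// matching flanks contributed by spurious chained anchors. Outputs the
// trimmed half-open ranges on s1 ([i0,i1)) and s2 ([j0,j1)) plus match and
// column counts inside the trimmed window.
static void banded_global(const std::string &s1, const std::string &s2,
                          double band_frac, int &matches, int &columns,
                          int &i0, int &i1, int &j0, int &j1) {
  const int m = (int)s1.size(), n = (int)s2.size();
  matches = 0; columns = 0; i0 = 0; i1 = m; j0 = 0; j1 = n;
  if (m == 0 || n == 0) { columns = std::max(m, n); return; }
  int band = std::max(16, (int)(band_frac * (double)std::max(m, n)));
  band = std::max(band, std::abs(m - n) + 16);
  const int W = 2 * band + 1;
  if ((double)(m + 1) * W > 4e8) stop("alignment span too large for banded DP");
  const int NEG = -1000000000;
  // center of band for row i: j = i * n / m
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<signed char> dir((size_t)(m + 1) * W, 0); // 1 diag, 2 up(gap in s2), 3 left(gap in s1)
  std::vector<int> center(m + 1);
  for (int i = 0; i <= m; ++i)
    center[i] = (int)(((long long)i * n) / m);
  // row 0
  for (int k = 0; k < W; ++k) {
    int j = center[0] - band + k;
    if (j < 0 || j > n) continue;
    prev[k] = -2 * j;
    if (j > 0) dir[k] = 3;
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int ci = center[i], cip = center[i - 1];
    for (int k = 0; k < W; ++k) {
      int j = ci - band + k;
      if (j < 0 || j > n) continue;
      int best = NEG; signed char d = 0;
      if (j >= 1) {
        int kp = (j - 1) - (cip - band);
        if (kp >= 0 && kp < W && prev[kp] > NEG) {
          int s = prev[kp] + ((s1[i - 1] == s2[j - 1] && base2bit(s1[i - 1]) >= 0) ? 1 : -1);
          if (s > best) { best = s; d = 1; }
        }
      }
      {
        int kp = j - (cip - band);
        if (kp >= 0 && kp < W && prev[kp] > NEG) {
          int s = prev[kp] - 2;
          if (s > best) { best = s; d = 2; }
        }
      }
      if (j >= 1 && k >= 1 && cur[k - 1] > NEG) {
        int s = cur[k - 1] - 2;
        if (s > best) { best = s; d = 3; }
      }
      cur[k] = best;
      dir[(size_t)i * W + k] = d;
    }
    prev.swap(cur);
  }
  // traceback from (m, n), collecting per-column scores in reverse
  std::vector<signed char> ops;   // 1 diag-match, 0 diag-mismatch, 2 up, 3 left
  ops.reserve(m + n);
  int i = m, j = n;
  bool clean = true;
  while (i > 0 || j > 0) {
    int k = j - (center[i] - band);
    signed char d = (k >= 0 && k < W) ? dir[(size_t)i * W + k] : 0;
    if (d == 1) {
      bool hit = (s1[i - 1] == s2[j - 1] && base2bit(s1[i - 1]) >= 0);
      ops.push_back(hit ? 1 : 0);
      --i; --j;
    } else if (d == 2) { ops.push_back(2); --i; }
    else if (d == 3) { ops.push_back(3); --j; }
    else { clean = false; break; } // off band: keep the untrimmed span
  }
  if (!clean) {
    // fall back: count the whole span as one block without trimming
    matches = 0; columns = m + n; i0 = 0; i1 = m; j0 = 0; j1 = n;
    return;
  }
  std::reverse(ops.begin(), ops.end());
  // Kadane over the path; track sequence offsets at every column boundary
  int run = 0, best = 0;
  int ci = 0, cj = 0;           // offsets after processing each op
  int start_i = 0, start_j = 0; // window start candidates
  int b_i0 = 0, b_i1 = 0, b_j0 = 0, b_j1 = 0;
  int cur_matches = 0, cur_cols = 0, b_matches = 0, b_cols = 0;
  for (size_t t = 0; t < ops.size(); ++t) {
    if (run <= 0) {
      run = 0; start_i = ci; start_j = cj;
      cur_matches = 0; cur_cols = 0;
    }
    run += (ops[t] == 1) ? 1 : ((ops[t] == 0) ? -1 : -2);
    cur_cols += 1;
    if (ops[t] == 1) cur_matches += 1;
    if (ops[t] == 1 || ops[t] == 0) { ++ci; ++cj; }
    else if (ops[t] == 2) ++ci;
    else ++cj;
    if (run > best) {
      best = run;
      b_i0 = start_i; b_j0 = start_j; b_i1 = ci; b_j1 = cj;
      b_matches = cur_matches; b_cols = cur_cols;
    }
  }
  if (best <= 0) { // nothing positive: degenerate empty hit
    matches = 0; columns = 0; i0 = i1 = 0; j0 = j1 = 0;
    return;
  }
  matches = b_matches; columns = b_cols;
  i0 = b_i0; i1 = b_i1; j0 = b_j0; j1 = b_j1;
}

// [[Rcpp::export]]
DataFrame cpp_chain_align(IntegerVector n_pos, IntegerVector o_pos,
                          IntegerVector strand, int w,
                          std::string nuc, std::string org,
                          int max_join_gap, double band_frac,
                          int xdrop, bool extend) {
  std::vector<Chain> chains;
  for (int sgn = 1; sgn >= -1; sgn -= 2) {
    std::vector<int> idx;
    for (int i = 0; i < n_pos.size(); ++i) if (strand[i] == sgn) idx.push_back(i);
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (n_pos[a] != n_pos[b]) return n_pos[a] < n_pos[b];
      return sgn > 0 ? (o_pos[a] < o_pos[b]) : (o_pos[a] > o_pos[b]);
    });
    std::vector<Chain> open, closed;
    for (size_t t = 0; t < idx.size(); ++t) {
      const int n = n_pos[idx[t]], o = o_pos[idx[t]];
      // retire chains that can no longer accept anchors (n is nondecreasing)
      for (size_t c = 0; c < open.size();) {
        if (n - (open[c].last_n + w) > max_join_gap) {
          closed.push_back(open[c]);
          open.erase(open.begin() + c);
        } else ++c;
      }
      int pick = -1;
      for (size_t c = 0; c < open.size(); ++c) {
        const Chain &ch = open[c];
        bool ok = (n >= ch.last_n) && (n - (ch.last_n + w) <= max_join_gap);
        if (ok) {
          if (sgn > 0)
            ok = (o >= ch.last_o) && (o - (ch.last_o + w) <= max_join_gap) &&
                 (n > ch.last_n || o > ch.last_o);
          else
            ok = (o <= ch.last_o) && (ch.last_o - (o + w) <= max_join_gap) &&
                 (n > ch.last_n || o < ch.last_o);
        }
        if (!ok) continue;
        if (pick < 0 || open[c].count > open[pick].count ||
            (open[c].count == open[pick].count && open[c].o_start < open[pick].o_start))
          pick = (int)c;
      }
      if (pick >= 0) {
        Chain &ch = open[pick];
        ch.n_end = std::max(ch.n_end, n + w);
        ch.o_start = std::min(ch.o_start, o);
        ch.o_end = std::max(ch.o_end, o + w);
        ch.last_n = n; ch.last_o = o; ch.count++;
      } else {
        Chain ch; ch.n_start = n; ch.n_end = n + w;
        ch.o_start = o; ch.o_end = o + w;
        ch.last_n = n; ch.last_o = o; ch.count = 1; ch.strand = sgn;
        open.push_back(ch);
      }
    }
    closed.insert(closed.end(), open.begin(), open.end());
    merge_pass(closed, max_join_gap);
    if (extend) {
      for (size_t c = 0; c < closed.size(); ++c) xdrop_extend(closed[c], nuc, org, xdrop);
      merge_pass(closed, max_join_gap);
    }
    chains.insert(chains.end(), closed.begin(), closed.end());
  }
  // Align each chained span and trim it to the maximal-scoring segment.
  // A chain can grab anchors of a shifted internal repeat and overshoot one
  // coordinate, in which case two trimmed hits cover the same insertion; a
  // second merge pass over the trimmed spans followed by realignment
  // collapses such duplicates.
  std::vector<int> hm_(chains.size()), hc_(chains.size());
  auto align_trim = [&](std::vector<Chain> &cs) {
    hm_.assign(cs.size(), 0); hc_.assign(cs.size(), 0);
    for (size_t h = 0; h < cs.size(); ++h) {
      Chain &c = cs[h];
      std::string s1 = nuc.substr(c.n_start, c.n_end - c.n_start);
      std::string s2 = org.substr(c.o_start, c.o_end - c.o_start);
      if (c.strand < 0) {
        std::string rc(s2.size(), 'N');
        for (size_t i = 0; i < s2.size(); ++i) rc[i] = compbase(s2[s2.size() - 1 - i]);
        s2 = rc;
      }
      int matches = 0, columns = 0, i0 = 0, i1 = 0, j0 = 0, j1 = 0;
      banded_global(s1, s2, band_frac, matches, columns, i0, i1, j0, j1);
      const int o_lo = c.o_start, o_hi = c.o_end;
      c.n_end = c.n_start + i1; c.n_start += i0;
      if (c.strand > 0) { c.o_start = o_lo + j0; c.o_end = o_lo + j1; }
      else { c.o_start = o_hi - j1; c.o_end = o_hi - j0; }
      hm_[h] = matches; hc_[h] = columns;
    }
    // drop empty trims
    std::vector<Chain> keep; std::vector<int> km, kc;
    for (size_t h = 0; h < cs.size(); ++h)
      if (cs[h].n_end > cs[h].n_start && cs[h].o_end > cs[h].o_start) {
        keep.push_back(cs[h]); km.push_back(hm_[h]); kc.push_back(hc_[h]);
      }
    cs.swap(keep); hm_.swap(km); hc_.swap(kc);
  };
  align_trim(chains);
  const size_t before = chains.size();
  {
    std::vector<Chain> merged = chains;
    merge_pass(merged, max_join_gap);
    if (merged.size() < before) {
      align_trim(merged);
      chains.swap(merged);
    }
  }
  const int H = (int)chains.size();
  IntegerVector hn1(H), hn2(H), ho1(H), ho2(H), hm(H), hc(H);
  CharacterVector hs(H);
  NumericVector hid(H);
  for (int h = 0; h < H; ++h) {
    hn1[h] = chains[h].n_start; hn2[h] = chains[h].n_end;
    ho1[h] = chains[h].o_start; ho2[h] = chains[h].o_end;
    hs[h] = chains[h].strand > 0 ? "+" : "-";
    hm[h] = hm_[h]; hc[h] = hc_[h];
    hid[h] = hc_[h] > 0 ? 100.0 * (double)hm_[h] / (double)hc_[h] : 0.0;
  }
  return DataFrame::create(
    _["n_start"] = hn1, _["n_end"] = hn2,
    _["o_start"] = ho1, _["o_end"] = ho2,
    _["strand"] = hs, _["matches"] = hm, _["columns"] = hc,
    _["identity_pct"] = hid, _["stringsAsFactors"] = false);
}
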