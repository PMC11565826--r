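#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Suffix array by prefix doubling with counting sort, O(n log n).
// txt holds positive integer codes; the terminal sentinel must be the unique
// lexicographically-least symbol so suffix comparisons are well defined.
// [[Rcpp::export]]
IntegerVector sa_build_cpp(IntegerVector txt) {
  const int n = txt.size();
  if (n == 0) return IntegerVector(0);
  int maxc = 0;
  for (int i = 0; i < n; ++i) maxc = std::max(maxc, txt[i]);
  int alphabet = std::max(maxc + 1, n + 1);
  std::vector<int> p(n), c(n), pn(n), cn(n), cnt(alphabet, 0);
  for (int i = 0; i < n; ++i) cnt[txt[i]]++;
  for (int i = 1; i < alphabet; ++i) cnt[i] += cnt[i - 1];
  for (int i = 0; i < n; ++i) p[--cnt[txt[i]]] = i;
  c[p[0]] = 0;
  int classes = 1;
  for (int i = 1; i < n; ++i) {
    if (txt[p[i]] != txt[p[i - 1]]) classes++;
    c[p[i]] = classes - 1;
  }
  for (int h = 0; (1 << h) < n; ++h) {
    const int len = 1 << h;
    for (int i = 0; i < n; ++i) {
      pn[i] = p[i] - len;
      if (pn[i] < 0) pn[i] += n;
    }
    std::fill(cnt.begin(), cnt.begin() + classes, 0);
    for (int i = 0; i < n; ++i) cnt[c[pn[i]]]++;
    for (int i = 1; i < classes; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) p[--cnt[c[pn[i]]]] = pn[i];
    cn[p[0]] = 0;
    classes = 1;
    for (int i = 1; i < n; ++i) {
      int a1 = c[p[i]], b1 = c[(p[i] + len) % n];
      int a2 = c[p[i - 1]], b2 = c[(p[i - 1] + len) % n];
      if (a1 != a2 || b1 != b2) classes++;
      cn[p[i]] = classes - 1;
    }
    std::swap(c, cn);
    if (classes == n) break;
  }
  IntegerVector sa(n);
  for (int i = 0; i < n; ++i) sa[i] = p[i];
  return sa;
}

// Kasai's LCP: lcp[i] = lcp(T[sa[i-1]..], T[sa[i]..]) for i > 0, lcp[0] = 0.
// [[Rcpp::export]]
IntegerVector lcp_kasai_cpp(IntegerVector txt, IntegerVector sa) {
  const int n = txt.size();
  IntegerVector lcp(n);
  if (n == 0) return lcp;
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i) rank[sa[i]] = i;
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (rank[i] == 0) { k = 0; lcp[0] = 0; continue; }
    int j = sa[rank[i] - 1];
    while (i + k < n && j + k < n && txt[i + k] == txt[j + k]) ++k;
    lcp[rank[i]] = k;
    if (k > 0) --k;
  }
  return lcp;
}

static inline int subrun_of(const IntegerVector& subStart, int p) {
  // index of the sub-run containing BWT position p (0-based)
  return int(std::upper_bound(subStart.begin(), subStart.end(), p) -
             subStart.begin()) - 1;
}

// One right-to-left pass computing pseudo-matching lengths and chain ids.
// All positions 0-based. Character codes are 1-based small integers; code
// nReset (the ambiguity symbol in reads) always forces a reset. Per-character
// navigation uses maximal-run tables: charRunFirst/charRunLast give the first
// and last BWT position of each maximal run of that character (sorted), and
// charThr the threshold position separating each consecutive run pair.
// [[Rcpp::export]]
List pml_query_cpp(IntegerVector pat,
                   IntegerVector subStart, IntegerVector subChar,
                   IntegerVector subId,
                   IntegerVector subLfPos, IntegerVector subLfDest,
                   List charRunFirst, List charRunLast, List charThr,
                   int nReset) {
  const int m = pat.size();
  const int rp = subStart.size();
  const int sigma = charRunFirst.size();
  IntegerVector pml(m), cid(m), trace(m);
  long steps = 0;
  int p = -1, cur = -1, ell = 0;
  bool first = true;
  for (int i = m - 1; i >= 0; --i) {
    const int c = pat[i];
    bool absent = (c == nReset) || c < 1 || c > sigma;
    IntegerVector rf;
    if (!absent) {
      rf = as<IntegerVector>(charRunFirst[c - 1]);
      if (rf.size() == 0) absent = true;
    }
    if (absent) {
      ell = 0; pml[i] = 0; cid[i] = 0; trace[i] = NA_INTEGER;
      continue;
    }
    int q;
    if (first) {
      // enter at the start of the last run of P[m]'s symbol
      q = rf[rf.size() - 1];
      cur = subrun_of(subStart, q);
      ell = 1;
      first = false;
    } else if (subChar[cur] == c) {
      q = p;
      ++ell;
    } else {
      // mismatch: threshold-directed jump to the nearest run of symbol c
      IntegerVector rl = as<IntegerVector>(charRunLast[c - 1]);
      IntegerVector th = as<IntegerVector>(charThr[c - 1]);
      int idx = int(std::upper_bound(rf.begin(), rf.end(), p) - rf.begin());
      if (idx == 0) q = rf[0];
      else if (idx == (int)rf.size()) q = rl[idx - 1];
      else q = (p >= th[idx - 1]) ? rf[idx] : rl[idx - 1];
      ++steps;
      cur = subrun_of(subStart, q);
      ell = 1;
    }
    // LF step from q (inside sub-run cur) using the run-indexed table
    p = subLfPos[cur] + (q - subStart[cur]);
    int k = subLfDest[cur];
    while (k + 1 < rp && subStart[k + 1] <= p) ++k;
    cur = k;
    ++steps;
    pml[i] = ell;
    cid[i] = subId[cur];
    trace[i] = p;
  }
  return List::create(_["pml"] = pml, _["cid"] = cid,
                      _["trace"] = trace, _["steps"] = (double)steps);
}

static int lcp_with_suffix(const IntegerVector& txt, int j,
                           const IntegerVector& pat, int i) {
  const int n = txt.size(), m = pat.size();
  int k = 0;
  while (j + k < n && i + k < m && txt[j + k] == pat[i + k]) ++k;
  return k;
}

// Exact matching statistics by per-suffix binary search over the suffix array.
// Returns, for every pattern position, the length of the longest prefix of
// P[i..m] occurring in the text and one 0-based occurrence position (-1 if 0).
// [[Rcpp::export]]
List ms_oracle_cpp(IntegerVector txt, IntegerVector sa, IntegerVector pat) {
  const int n = txt.size(), m = pat.size();
  IntegerVector len(m), pos(m);
  for (int i = 0; i < m; ++i) {
    // lower bound of pattern suffix among text suffixes
    int lo = 0, hi = n;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      int j = sa[mid], k = 0;
      bool less = false;  // suffix(j) < pat[i..]?
      while (true) {
        if (i + k >= m) { less = false; break; }       // pat exhausted: suffix >= pat
        if (j + k >= n) { less = true; break; }        // text suffix is a proper prefix
        if (txt[j + k] < pat[i + k]) { less = true; break; }
        if (txt[j + k] > pat[i + k]) { less = false; break; }
        ++k;
      }
      if (less) lo = mid + 1; else hi = mid;
    }
    int best = 0, bestPos = -1;
    for (int cand = lo - 1; cand <= lo; ++cand) {
      if (cand < 0 || cand >= n) continue;
      int l = lcp_with_suffix(txt, sa[cand], pat, i);
      if (l > best) { best = l; bestPos = sa[cand]; }
    }
    len[i] = best;
    pos[i] = bestPos;
  }
  return List::create(_["len"] = len, _["pos"] = pos);
}
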