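#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// LZ76 exhaustive-history phrase count. Scanning left to right, the current
// phrase is extended while it occurs as a substring of everything seen so
// far minus the phrase's last symbol (previous occurrences may overlap the
// phrase), and is closed at the first novelty; the trailing, possibly
// non-novel phrase counts as one.
//
// Implemented in linear-ish time via the longest-previous-factor (LPF)
// array: phrase length at position p is LPF[p] + 1, since the phrase can be
// copied for exactly LPF[p] symbols before a novel one is needed. LPF is
// computed from a suffix array (prefix-doubling construction), Kasai's LCP
// array, and the Crochemore-Ilie stack pass.

static std::vector<int> suffix_array(const std::vector<int>& s) {
  const int n = s.size();
  std::vector<int> sa(n), rank_(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rank_[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      int ra = a + k < n ? rank_[a + k] : -1;
      int rb = b + k < n ? rank_[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    }
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai: lcp[r] = longest common prefix of suffixes sa[r-1] and sa[r]
static std::vector<int> lcp_array(const std::vector<int>& s,
                                  const std::vector<int>& sa) {
  const int n = s.size();
  std::vector<int> rank_(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// Crochemore & Ilie (2008): LPF[i] = length of the longest factor starting
// at i that also starts at some j < i (overlap allowed)
static std::vector<int> lpf_array(const std::vector<int>& sa,
                                  std::vector<int> lcp) {
  const int n = sa.size();
  std::vector<int> lpf(n, 0);
  std::vector<std::pair<int, int>> stack; // (sa value, lcp value)
  stack.reserve(n);
  for (int i = 0; i <= n; ++i) {
    int cur_sa = (i < n) ? sa[i] : -1;
    int cur_lcp = (i < n) ? lcp[i] : 0;
    while (!stack.empty() && cur_sa < stack.back().first) {
      int sa_t = stack.back().first;
      int lcp_t = stack.back().second;
      stack.pop_back();
      lpf[sa_t] = std::max(lcp_t, cur_lcp);
      cur_lcp = std::min(lcp_t, cur_lcp);
    }
    if (i < n) stack.emplace_back(cur_sa, cur_lcp);
  }
  return lpf;
}

// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(const IntegerVector& bits) {
  const int n = bits.size();
  if (n == 0) stop("empty bit sequence");
  if (n == 1) return 1;
  std::vector<int> s(bits.begin(), bits.end());
  std::vector<int> sa = suffix_array(s);
  std::vector<int> lpf = lpf_array(sa, lcp_array(s, sa));
  int c = 0;
  long long p = 0;
  while (p < n) {
    ++c;
    p += static_cast<long long>(lpf[p]) + 1; // may overshoot: partial tail = 1
  }
  return c;
}
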