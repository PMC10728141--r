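#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3' read trimming: adapter (leftmost full occurrence or suffix overlap with
// an adapter prefix reaching the read end), terminal poly-G runs, then
// trailing low-quality bases. Applied to a fixpoint so the operation is
// idempotent by construction.
// [[Rcpp::export]]
List trim_reads_cpp(CharacterVector seq, CharacterVector qual, int trim_q,
                    CharacterVector adapters, int min_polyg,
                    int min_adapter_overlap) {
  int n = seq.size();
  CharacterVector oseq(n), oqual(n);
  std::vector<std::string> ad;
  for (int a = 0; a < adapters.size(); ++a)
    ad.push_back(as<std::string>(adapters[a]));
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seq[i]);
    std::string q = as<std::string>(qual[i]);
    bool changed = true;
    while (changed && !s.empty()) {
      changed = false;
      // adapter: cut at the leftmost position where the remainder of the
      // read matches a prefix of an adapter (full hit, or an overlap of at
      // least min_adapter_overlap reaching the 3' end)
      size_t best = std::string::npos;
      for (size_t a = 0; a < ad.size(); ++a) {
        const std::string &ap = ad[a];
        if (ap.empty()) continue;
        for (size_t p = 0; p < s.size(); ++p) {
          size_t len = std::min(s.size() - p, ap.size());
          bool reaches_end = (s.size() - p) <= ap.size();
          if (len < ap.size() && !reaches_end) continue;
          if (reaches_end && len < (size_t)min_adapter_overlap) break;
          if (s.compare(p, len, ap, 0, len) == 0) {
            if (p < best) best = p;
            break;
          }
        }
      }
      if (best != std::string::npos) {
        s.erase(best); q.erase(best);
        changed = true;
        if (s.empty()) break;
      }
      // terminal poly-G run (two-channel chemistry artifact)
      size_t g = 0;
      while (g < s.size() && s[s.size() - 1 - g] == 'G') ++g;
      if ((int)g >= min_polyg) {
        s.erase(s.size() - g); q.erase(q.size() - g);
        changed = true;
        if (s.empty()) break;
      }
      // trailing low-quality bases
      size_t t = 0;
      while (t < q.size() && (int)(q[q.size() - 1 - t]) - 33 < trim_q) ++t;
      if (t > 0) {
        s.erase(s.size() - t); q.erase(q.size() - t);
        changed = true;
      }
    }
    oseq[i] = s; oqual[i] = q;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual);
}

// Mismatch count of query i placed gaplessly on ref at 0-based offset
// start0[i]; NA when the placement runs off the reference.
// [[Rcpp::export]]
IntegerVector hamming_at_cpp(std::string ref, IntegerVector start0,
                             CharacterVector query) {
  int n = start0.size();
  IntegerVector out(n);
  int L = ref.size();
  for (int i = 0; i < n; ++i) {
    std::string qs = as<std::string>(query[i]);
    int s = start0[i];
    if (s < 0 || s + (int)qs.size() > L) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t j = 0; j < qs.size(); ++j)
      if (qs[j] != ref[s + j]) ++d;
    out[i] = d;
  }
  return out;
}

// Suffix array over an integer text by prefix doubling. Terminators are
// encoded by the caller as distinct values below the letter codes, so the
// sort over the concatenated read collection is the generalized suffix
// array that defines the eBWT.
// [[Rcpp::export]]
IntegerVector suffix_array_cpp(IntegerVector text) {
  int n = text.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = text[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sa[i];
  return out;
}

// Kasai's algorithm; lcp[i] = longest common prefix of suffixes sa[i-1] and
// sa[i] (lcp[0] = 0).
// [[Rcpp::export]]
IntegerVector lcp_kasai_cpp(IntegerVector text, IntegerVector sa) {
  int n = text.size();
  std::vector<int> rank_(n);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  IntegerVector lcp(n);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && text[i + h] == text[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}
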