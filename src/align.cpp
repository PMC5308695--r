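// Alignment inner loops: FM-index (BWT) seed search with bounded
// substitution backtracking, and Smith-Waterman local alignment with flat
// per-base indel penalties (no open/extend distinction) and full traceback.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
List cpp_fm_build(std::string ref) {
  const int n = (int)ref.size() + 1; // sentinel included
  std::vector<int> sa(n);
  for (int i = 0; i < n; ++i) sa[i] = i;
  const char* s = ref.c_str();
  const int len = (int)ref.size();
  std::sort(sa.begin(), sa.end(), [&](int a, int b) {
    // suffix compare with implicit '$' (smaller than any base) at position len
    while (a < len && b < len) {
      if (s[a] != s[b]) return s[a] < s[b];
      ++a; ++b;
    }
    return a > b; // shorter suffix (hits sentinel first) sorts first
  });
  std::vector<int> bwt(n); // -1 for sentinel
  for (int i = 0; i < n; ++i) {
    int p = sa[i] == 0 ? n - 1 : sa[i] - 1;
    bwt[i] = (p == len) ? -1 : base_code(s[p]);
  }
  // occ[(i+1)*4 + c] = count of base c in bwt[0..i]
  IntegerVector occ((n + 1) * 4);
  int cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    if (bwt[i] >= 0) cnt[bwt[i]]++;
    for (int c = 0; c < 4; ++c) occ[(i + 1) * 4 + c] = cnt[c];
  }
  IntegerVector C(5); // first index of each base in sorted column; C[0] for 'A'
  int tot[4] = {0, 0, 0, 0};
  for (int i = 0; i < len; ++i) tot[base_code(s[i])]++;
  C[0] = 1; // sentinel occupies row 0
  for (int c = 1; c < 4; ++c) C[c] = C[c - 1] + tot[c - 1];
  C[4] = C[3] + tot[3];
  return List::create(_["sa"] = IntegerVector(sa.begin(), sa.end()),
                      _["occ"] = occ, _["C"] = C, _["n"] = n);
}

static void fm_rec(const std::string& q, int i, int sp, int ep, int mm,
                   int max_mm, const int* occ, const int* C,
                   std::vector<std::pair<int, int> >& hits) {
  if (sp > ep) return;
  if (i < 0) {
    hits.push_back(std::make_pair(sp, ep));
    return;
  }
  int qc = base_code(q[i]);
  for (int c = 0; c < 4; ++c) {
    int mm2 = mm + (c == qc ? 0 : 1);
    if (mm2 > max_mm) continue;
    int sp2 = C[c] + occ[sp * 4 + c];
    int ep2 = C[c] + occ[(ep + 1) * 4 + c] - 1;
    if (sp2 <= ep2) fm_rec(q, i - 1, sp2, ep2, mm2, max_mm, occ, C, hits);
  }
}

// start positions (0-based) of approximate occurrences of query in the
// indexed reference, allowing up to max_mm substitutions
// [[Rcpp::export]]
IntegerVector cpp_fm_search(List idx, std::string query, int max_mm) {
  IntegerVector sa = idx["sa"];
  IntegerVector occ = idx["occ"];
  IntegerVector C = idx["C"];
  int n = as<int>(idx["n"]);
  for (size_t i = 0; i < query.size(); ++i) {
    if (base_code(query[i]) < 0) return IntegerVector(0);
  }
  std::vector<std::pair<int, int> > hits;
  fm_rec(query, (int)query.size() - 1, 0, n - 1, 0, max_mm,
         occ.begin(), C.begin(), hits);
  std::vector<int> pos;
  for (size_t h = 0; h < hits.size(); ++h) {
    for (int r = hits[h].first; r <= hits[h].second; ++r) pos.push_back(sa[r]);
  }
  std::sort(pos.begin(), pos.end());
  pos.erase(std::unique(pos.begin(), pos.end()), pos.end());
  return IntegerVector(pos.begin(), pos.end());
}

// Smith-Waterman local alignment of read vs window, flat indel penalty.
// Returns score, ops string over M/X/I/D/S (M = identical, X = mismatch),
// and 0-based window offset of the first aligned base.
// Tie-breaks are deterministic: best cell = highest score, then smallest
// window column, then smallest read row; traceback prefers diagonal, then
// deletion (gap in read), then insertion.
// [[Rcpp::export]]
List cpp_sw(std::string read, std::string window, double match,
            double mismatch, double indel) {
  const int m = (int)read.size();
  const int n = (int)window.size();
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double diag = H[(i - 1) * (n + 1) + (j - 1)] +
                    (read[i - 1] == window[j - 1] ? match : mismatch);
      double up = H[(i - 1) * (n + 1) + j] + indel;   // insertion (read base)
      double left = H[i * (n + 1) + (j - 1)] + indel; // deletion (ref base)
      double v = std::max(0.0, std::max(diag, std::max(up, left)));
      H[i * (n + 1) + j] = v;
      if (v > best || (v == best && (j < bj || (j == bj && i < bi)))) {
        if (v > 0) { best = v; bi = i; bj = j; }
      }
    }
  }
  std::string ops_rev;
  int i = bi, j = bj;
  if (best > 0) {
    while (i > 0 && j > 0) {
      double v = H[i * (n + 1) + j];
      if (v == 0) break;
      double diag = H[(i - 1) * (n + 1) + (j - 1)] +
                    (read[i - 1] == window[j - 1] ? match : mismatch);
      double left = H[i * (n + 1) + (j - 1)] + indel;
      if (v == diag) {
        ops_rev.push_back(read[i - 1] == window[j - 1] ? 'M' : 'X');
        --i; --j;
      } else if (v == left) {
        ops_rev.push_back('D');
        --j;
      } else {
        ops_rev.push_back('I');
        --i;
      }
    }
  }
  // run-length encode, adding soft clips for unaligned read ends
  std::string ops;
  int lead = (best > 0) ? i : m;
  int trail = (best > 0) ? m - bi : 0;
  std::vector<std::pair<char, int> > runs;
  if (lead > 0) runs.push_back(std::make_pair('S', lead));
  for (int k = (int)ops_rev.size() - 1; k >= 0; --k) {
    char op = ops_rev[k];
    if (!runs.empty() && runs.back().first == op) runs.back().second++;
    else runs.push_back(std::make_pair(op, 1));
  }
  if (trail > 0) runs.push_back(std::make_pair('S', trail));
  std::string out;
  for (size_t k = 0; k < runs.size(); ++k) {
    out += std::to_string(runs[k].second);
    out.push_back(runs[k].first);
  }
  return List::create(_["score"] = best, _["ops"] = out,
                      _["window_offset"] = (best > 0 ? j : 0));
}
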