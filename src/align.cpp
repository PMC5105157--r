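#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Semi-global alignment of short reads against a small in-memory reference
// panel: the read is consumed end-to-end, the reference start/end are free.
// Two exact strategies produce identical hit sets:
//  - full dynamic programming over every reference column, O(m*n) per
//    read/reference/strand;
//  - pigeonhole seed-and-verify: an alignment with at most k edits must
//    contain one of k+1 contiguous read pieces exactly, so 11-mer seed
//    lookups locate every candidate window and windowed DP verifies them.
// The seeded path is used whenever every piece provides a clean seed;
// otherwise the full scan runs. Both are exposed to R so tests can assert
// equivalence.

static const int SEED_LEN = 11;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// 11-mer position index over one reference
struct SeedIndex {
  std::unordered_map<uint32_t, std::vector<int32_t>> pos;
  void build(const std::string &ref) {
    const int n = (int)ref.size();
    if (n < SEED_LEN) return;
    uint32_t key = 0;
    int run = 0;  // length of current clean (ACGT) run
    const uint32_t mask = (1u << (2 * SEED_LEN)) - 1u;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(ref[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)c) & mask;
      if (++run >= SEED_LEN) pos[key].push_back(i - SEED_LEN + 1);
    }
  }
};

// pack the SEED_LEN-mer starting at `off`; false if it touches a non-ACGT base
static bool pack_seed(const std::string &s, int off, uint32_t &key) {
  if (off + SEED_LEN > (int)s.size()) return false;
  uint32_t k = 0;
  for (int i = 0; i < SEED_LEN; ++i) {
    const int c = base_code(s[off + i]);
    if (c < 0) return false;
    k = (k << 2) | (uint32_t)c;
  }
  key = k;
  return true;
}

// Exact DP over the window ref[lo, end) for an alignment ending at `end`
// (0-based exclusive), free start: returns the true minimal edit distance
// and, via traceback, the 0-based start and CIGAR. Tie-break order is
// deterministic: diagonal (M), then read-consuming gap (I), then
// reference-consuming gap (D).
static int traceback_window(const std::string &read, const std::string &ref,
                            int lo, int end, int &ref_start, std::string &cigar) {
  const int m = (int)read.size();
  const int L = end - lo;
  std::vector<int> D((size_t)(m + 1) * (L + 1));
  auto at = [&](int i, int j) -> int & { return D[(size_t)i * (L + 1) + j]; };
  for (int j = 0; j <= L; ++j) at(0, j) = 0;
  for (int i = 1; i <= m; ++i) {
    at(i, 0) = i;
    for (int j = 1; j <= L; ++j) {
      int sub = at(i - 1, j - 1) + (read[i - 1] == ref[lo + j - 1] ? 0 : 1);
      const int ins = at(i - 1, j) + 1;
      const int del = at(i, j - 1) + 1;
      int v = sub < ins ? sub : ins;
      if (del < v) v = del;
      at(i, j) = v;
    }
  }
  std::string ops;
  int i = m, j = L;
  while (i > 0) {
    if (j > 0 && at(i, j) == at(i - 1, j - 1) + (read[i - 1] == ref[lo + j - 1] ? 0 : 1)) {
      ops.push_back('M'); --i; --j;
    } else if (at(i, j) == at(i - 1, j) + 1) {
      ops.push_back('I'); --i;
    } else {
      ops.push_back('D'); --j;
    }
  }
  ref_start = lo + j;
  std::string cg;
  for (int k = (int)ops.size() - 1; k >= 0;) {
    int k2 = k;
    while (k2 >= 0 && ops[k2] == ops[k]) --k2;
    cg += std::to_string(k - k2);
    cg.push_back(ops[k]);
    k = k2;
  }
  cigar = cg;
  return at(m, L);
}

// column-sweep DP over ref[lo, hi): append every end position (0-based
// exclusive, global coordinates) whose bottom-row score is <= k
static void sweep_ends(const std::string &rd, const std::string &ref,
                       int lo, int hi, int k, std::vector<int> &ends) {
  const int m = (int)rd.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int i = 0; i <= m; ++i) prev[i] = i;
  for (int j = lo + 1; j <= hi; ++j) {
    cur[0] = 0;
    const char fb = ref[j - 1];
    for (int i = 1; i <= m; ++i) {
      int v = prev[i - 1] + (rd[i - 1] == fb ? 0 : 1);
      const int ins = cur[i - 1] + 1;
      const int del = prev[i] + 1;
      if (ins < v) v = ins;
      if (del < v) v = del;
      cur[i] = v;
    }
    if (cur[m] <= k) ends.push_back(j);
    std::swap(prev, cur);
  }
}

// candidate ends via pigeonhole seeds; returns false when the seeded
// strategy cannot guarantee completeness for this read (piece too short for
// a seed, or non-ACGT bases in every usable position)
static bool seeded_ends(const std::string &rd, const std::string &ref,
                        const SeedIndex &idx, int k, std::vector<int> &ends) {
  const int m = (int)rd.size();
  const int npiece = k + 1;
  if (m / npiece < SEED_LEN) return false;
  // balanced contiguous pieces; seed = first SEED_LEN bases of each piece
  std::vector<std::pair<int, int>> windows;  // [lo, hi) in ref coordinates
  for (int p = 0; p < npiece; ++p) {
    const int off = (int)(((long long)p * m) / npiece);
    uint32_t key;
    if (!pack_seed(rd, off, key)) return false;  // stay exact: fall back
    auto it = idx.pos.find(key);
    if (it == idx.pos.end()) continue;
    for (int q : it->second) {
      const int diag = q - off;
      const int lo = std::max(0, diag - k);
      const int hi = std::min((int)ref.size(), diag + m + 2 * k);
      if (hi > lo) windows.emplace_back(lo, hi);
    }
  }
  if (windows.empty()) return true;
  std::sort(windows.begin(), windows.end());
  // merge overlapping windows, then sweep each once
  int lo = windows[0].first, hi = windows[0].second;
  for (size_t w = 1; w < windows.size(); ++w) {
    if (windows[w].first <= hi) {
      hi = std::max(hi, windows[w].second);
    } else {
      sweep_ends(rd, ref, lo, hi, k, ends);
      lo = windows[w].first; hi = windows[w].second;
    }
  }
  sweep_ends(rd, ref, lo, hi, k, ends);
  std::sort(ends.begin(), ends.end());
  ends.erase(std::unique(ends.begin(), ends.end()), ends.end());
  return true;
}

static DataFrame align_impl(CharacterVector read_ids, CharacterVector reads,
                            CharacterVector ref_names, CharacterVector refs,
                            IntegerVector max_edits, bool force_full) {
  const int n_reads = reads.size();
  const int n_refs = refs.size();
  if (max_edits.size() != n_reads && max_edits.size() != 1)
    stop("max_edits must have length 1 or length(reads)");

  std::vector<std::string> ref_seq(n_refs);
  std::vector<SeedIndex> idx(n_refs);
  for (int r = 0; r < n_refs; ++r) {
    ref_seq[r] = as<std::string>(refs[r]);
    if (!force_full) idx[r].build(ref_seq[r]);
  }

  std::vector<std::string> out_read, out_ref, out_cigar;
  std::vector<int> out_start, out_end, out_dist, out_len;
  std::vector<char> out_strand;

  for (int q = 0; q < n_reads; ++q) {
    const std::string fwd = as<std::string>(reads[q]);
    const int m = (int)fwd.size();
    if (m == 0) continue;
    const int k = max_edits.size() == 1 ? max_edits[0] : max_edits[q];
    if (k < 0) continue;
    const std::string rev = revcomp(fwd);
    const std::string rid = as<std::string>(read_ids[q]);

    for (int r = 0; r < n_refs; ++r) {
      const std::string &ref = ref_seq[r];
      for (int s = 0; s < 2; ++s) {
        const std::string &rd = (s == 0) ? fwd : rev;
        std::vector<int> ends;
        bool ok = false;
        if (!force_full) ok = seeded_ends(rd, ref, idx[r], k, ends);
        if (!ok) {
          ends.clear();
          sweep_ends(rd, ref, 0, (int)ref.size(), k, ends);
        }
        for (int end : ends) {
          int ref_start0;
          std::string cg;
          const int lo = std::max(0, end - m - k);
          const int d = traceback_window(rd, ref, lo, end, ref_start0, cg);
          if (d > k) continue;  // windowed sweep may over-call near margins
          out_read.push_back(rid);
          out_ref.push_back(as<std::string>(ref_names[r]));
          out_strand.push_back(s == 0 ? '+' : '-');
          out_start.push_back(ref_start0 + 1);  // 1-based
          out_end.push_back(end);
          out_dist.push_back(d);
          out_cigar.push_back(cg);
          out_len.push_back(m);
        }
      }
    }
  }

  const R_xlen_t nh = (R_xlen_t)out_read.size();
  CharacterVector rid(nh), racc(nh), rcig(nh), rstr(nh);
  IntegerVector rst(nh), ren(nh), rnm(nh), rlen(nh);
  for (R_xlen_t i = 0; i < nh; ++i) {
    rid[i] = out_read[i];
    racc[i] = out_ref[i];
    rstr[i] = std::string(1, out_strand[i]);
    rst[i] = out_start[i];
    ren[i] = out_end[i];
    rnm[i] = out_dist[i];
    rcig[i] = out_cigar[i];
    rlen[i] = out_len[i];
  }
  return DataFrame::create(
      _["read_id"] = rid, _["ref_accession"] = racc, _["strand"] = rstr,
      _["ref_start"] = rst, _["ref_end"] = ren, _["edit_distance"] = rnm,
      _["cigar"] = rcig, _["read_len"] = rlen,
      _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame semiglobal_align_cpp(CharacterVector read_ids, CharacterVector reads,
                               CharacterVector ref_names, CharacterVector refs,
                               IntegerVector max_edits) {
  return align_impl(read_ids, reads, ref_names, refs, max_edits, false);
}

// full-scan variant kept as the independent route for equivalence tests
// [[Rcpp::export]]
DataFrame semiglobal_align_full_cpp(CharacterVector read_ids, CharacterVector reads,
                                    CharacterVector ref_names, CharacterVector refs,
                                    IntegerVector max_edits) {
  return align_impl(read_ids, reads, ref_names, refs, max_edits, true);
}

// DUST-style low-complexity score. For each sliding window of length
// w = min(64, len): with triplet counts c_t over overlapping trinucleotides
// (triplets containing a non-ACGT base do not count), the window score is
// [sum_t c_t (c_t - 1) / 2] / (w - 3); the read score is the max over windows.
// Sequences shorter than 3 score 0.
// [[Rcpp::export]]
NumericVector dust_score_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  NumericVector out(n);

  for (int q = 0; q < n; ++q) {
    const std::string s = as<std::string>(seqs[q]);
    const int len = (int)s.size();
    if (len < 3) { out[q] = 0.0; continue; }
    const int w = std::min(64, len);
    const int ntrip = len - 2;
    std::vector<int> trip(ntrip);
    for (int i = 0; i < ntrip; ++i) {
      const int a = base_code(s[i]), b = base_code(s[i + 1]), c = base_code(s[i + 2]);
      trip[i] = (a < 0 || b < 0 || c < 0) ? -1 : (a << 4) | (b << 2) | c;
    }
    const int wt = w - 2;  // triplets per window
    std::vector<int> cnt(64, 0);
    long pairs = 0;  // sum c(c-1)/2, updated incrementally
    for (int i = 0; i < wt; ++i)
      if (trip[i] >= 0) { pairs += cnt[trip[i]]; ++cnt[trip[i]]; }
    double best = (double)pairs / (w - 3);
    for (int start = 1; start + w <= len; ++start) {
      const int drop = trip[start - 1], add = trip[start + w - 3];
      if (drop >= 0) { --cnt[drop]; pairs -= cnt[drop]; }
      if (add >= 0) { pairs += cnt[add]; ++cnt[add]; }
      const double sc = (double)pairs / (w - 3);
      if (sc > best) best = sc;
    }
    out[q] = best;
  }
  return out;
}
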