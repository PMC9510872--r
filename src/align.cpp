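#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap Smith-Waterman with full traceback (Gotoh).
// Gap of length L costs gap_open + L * gap_ext.
// CIGAR ops: '=' match, 'X' mismatch, 'I' query base over target gap,
// 'D' target base over query gap. Coordinates returned 0-based half-open.

namespace {

inline int score_pair(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch; // N never matches
  return (a == b) ? match : mismatch;
}

// traceback byte layout: bits 0-1 H-source (0 stop, 1 diag, 2 E(=D), 3 F(=I));
// bit 2: E opened from H; bit 3: F opened from H.
const uint8_t H_STOP = 0, H_DIAG = 1, H_E = 2, H_F = 3;

} // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string t,
                  int match = 1, int mismatch = -2,
                  int gap_open = 3, int gap_ext = 1) {
  const size_t n = q.size(), m = t.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("alignment problem too large (%d x %d)", (int)n, (int)m);

  const int NEG = -1000000000;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG); // gap in query (D)
  std::vector<int> F(m + 1, NEG);                       // gap in target (I)
  std::vector<uint8_t> tb((n + 1) * (m + 1), 0);

  int best = 0; size_t bi = 0, bj = 0;
  for (size_t i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG;
    for (size_t j = 1; j <= m; ++j) {
      uint8_t cell = 0;
      // E: gap in query, consumes target (D op), horizontal
      int e_open = Hcur[j - 1] - gap_open - gap_ext;
      int e_ext  = Ecur[j - 1] - gap_ext;
      if (e_open >= e_ext) { Ecur[j] = e_open; cell |= 4; }
      else                 { Ecur[j] = e_ext; }
      // F: gap in target, consumes query (I op), vertical
      int f_open = Hprev[j] - gap_open - gap_ext;
      int f_ext  = F[j] - gap_ext;
      if (f_open >= f_ext) { F[j] = f_open; cell |= 8; }
      else                 { F[j] = f_ext; }
      int diag = Hprev[j - 1] + score_pair(q[i - 1], t[j - 1], match, mismatch);
      int h = 0; uint8_t src = H_STOP;
      if (diag > h)    { h = diag;    src = H_DIAG; }
      if (Ecur[j] > h) { h = Ecur[j]; src = H_E; }
      if (F[j] > h)    { h = F[j];    src = H_F; }
      Hcur[j] = h;
      tb[i * (m + 1) + j] = cell | src;
      // strict > keeps the earliest (leftmost target end) best cell
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  if (best <= 0)
    return List::create(_["score"] = 0, _["found"] = false);

  // traceback
  size_t i = bi, j = bj;
  std::string ops; // reversed
  int matches = 0, mismatches = 0, ins = 0, del = 0;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (true) {
    uint8_t cell = tb[i * (m + 1) + j];
    if (state == 0) {
      uint8_t src = cell & 3;
      if (src == H_STOP) break;
      if (src == H_DIAG) {
        bool is_match = (q[i - 1] == t[j - 1]) && q[i - 1] != 'N';
        ops.push_back(is_match ? '=' : 'X');
        if (is_match) ++matches; else ++mismatches;
        --i; --j;
      } else if (src == H_E) state = 1;
      else state = 2;
    } else if (state == 1) { // E: D op, consume target
      ops.push_back('D'); ++del;
      bool opened = (cell & 4) != 0;
      --j;
      if (opened) state = 0;
    } else {                 // F: I op, consume query
      ops.push_back('I'); ++ins;
      bool opened = (cell & 8) != 0;
      --i;
      if (opened) state = 0;
    }
  }

  // compress reversed ops into CIGAR
  std::string cigar;
  size_t len = ops.size();
  size_t p = len;
  while (p > 0) {
    char op = ops[p - 1];
    size_t cnt = 0;
    while (p > 0 && ops[p - 1] == op) { ++cnt; --p; }
    cigar += std::to_string(cnt);
    cigar.push_back(op);
  }

  return List::create(
    _["score"] = best, _["found"] = true,
    _["q_start"] = (int)i, _["q_end"] = (int)bi,
    _["t_start"] = (int)j, _["t_end"] = (int)bj,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["insertions"] = ins, _["deletions"] = del,
    _["cigar"] = cigar);
}

// Exact k-mer seed matches between query and target (forward strands).
// Returns a 2-column integer matrix of 0-based (q_pos, t_pos) pairs.
// k-mers containing non-ACGT characters are skipped.

// [[Rcpp::export(name = ".find_seeds_cpp")]]
IntegerMatrix find_seeds_cpp(std::string q, std::string t, int k = 15) {
  if (k < 4 || k > 31) stop("seed k must be in [4, 31]");
  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::unordered_map<uint64_t, std::vector<int>> idx;
  uint64_t h = 0; int run = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    int c = code(q[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[h].push_back((int)(i + 1 - k));
  }
  std::vector<int> qs, ts;
  h = 0; run = 0;
  for (size_t i = 0; i < t.size(); ++i) {
    int c = code(t[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto it = idx.find(h);
      if (it != idx.end()) {
        int tp = (int)(i + 1 - k);
        for (int qp : it->second) { qs.push_back(qp); ts.push_back(tp); }
      }
    }
  }
  IntegerMatrix out(qs.size(), 2);
  for (size_t r = 0; r < qs.size(); ++r) { out(r, 0) = qs[r]; out(r, 1) = ts[r]; }
  colnames(out) = CharacterVector::create("q_pos", "t_pos");
  return out;
}
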