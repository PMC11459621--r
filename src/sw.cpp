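#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Bisulfite-aware match test. mode: 0 = off, 1 = CT (ref C matches read T),
// 2 = GA (ref G matches read A). N never matches anything.
static inline bool is_match(char q, char t, int mode) {
  if (q == 'N' || t == 'N') return false;
  if (q == t) return true;
  if (mode == 1 && t == 'C' && q == 'T') return true;
  if (mode == 2 && t == 'G' && q == 'A') return true;
  return false;
}

// Alignment provenance packed into one orderable 64-bit word:
// start_t (high) | start_q | gap count (low 20 bits).  Smaller is
// preferred, giving the tie-break order: smallest target start, then
// smallest query start, then fewest gapped bases.
static inline uint64_t fresh_rank(int t, int q) {
  return ((uint64_t)t << 40) | ((uint64_t)q << 20);
}

// Smith-Waterman local alignment, linear gap penalty, all cells floored at
// 0.  Deterministic: co-optimal alignments resolve by smallest target
// start, then smallest query start, then fewest gaps, then smallest end
// coordinates.  Returns 0-based half-open offsets and a CIGAR over the
// aligned region (M = aligned pair incl. mismatch, I = query base skipped
// in target, D = target base skipped in query).
// [[Rcpp::export]]
List cpp_sw_local(std::string query, std::string target,
                  int match, int mismatch, int gap, int mode) {
  const int nq = (int)query.size(), nt = (int)target.size();
  const int W = nt + 1;

  std::vector<int> Sprev(W), Scur(W);
  std::vector<uint64_t> Rprev(W), Rcur(W);
  std::vector<uint8_t> MV((size_t)(nq + 1) * W, 0); // 0 start,1 diag,2 I,3 D
  std::vector<int> sub(W);

  for (int j = 0; j < W; ++j) { Sprev[j] = 0; Rprev[j] = fresh_rank(j, 0); }

  int best = 0, b_i = 0, b_j = 0;
  uint64_t b_rank = ~0ULL;
  bool have_best = false;

  for (int i = 1; i <= nq; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= nt; ++j) {
      sub[j] = is_match(qc, target[j - 1], mode) ? match : mismatch;
    }
    Scur[0] = 0; Rcur[0] = fresh_rank(0, i);
    uint8_t *mvrow = &MV[(size_t)i * W];
    for (int j = 1; j <= nt; ++j) {
      int sc = Sprev[j - 1] + sub[j];
      uint64_t rk = Rprev[j - 1];
      uint8_t mv = 1;

      int alt = Scur[j - 1] + gap;          // D: target base skipped
      uint64_t ark = Rcur[j - 1] + 1;
      if (alt > sc || (alt == sc && ark < rk)) { sc = alt; rk = ark; mv = 3; }

      alt = Sprev[j] + gap;                 // I: query base skipped
      ark = Rprev[j] + 1;
      if (alt > sc || (alt == sc && ark < rk)) { sc = alt; rk = ark; mv = 2; }

      if (sc <= 0) { sc = 0; rk = fresh_rank(j, i); mv = 0; }
      Scur[j] = sc; Rcur[j] = rk; mvrow[j] = mv;

      if (sc > 0 &&
          (sc > best || (have_best && sc == best && rk < b_rank))) {
        best = sc; b_rank = rk; b_i = i; b_j = j; have_best = true;
      }
    }
    std::swap(Sprev, Scur);
    std::swap(Rprev, Rcur);
  }

  if (!have_best) {
    return List::create(_["score"] = 0, _["q_off"] = 0, _["t_off"] = 0,
                        _["q_end"] = 0, _["t_end"] = 0,
                        _["cigar"] = "", _["ngaps"] = 0);
  }

  // traceback along the stored moves
  std::string ops;
  int i = b_i, j = b_j, ngaps = 0;
  while (i > 0 && j > 0) {
    const uint8_t mv = MV[(size_t)i * W + j];
    if (mv == 1) { ops.push_back('M'); --i; --j; }
    else if (mv == 2) { ops.push_back('I'); --i; ++ngaps; }
    else if (mv == 3) { ops.push_back('D'); --j; ++ngaps; }
    else break;
  }
  std::string cigar;
  for (int p = (int)ops.size() - 1; p >= 0;) {
    char op = ops[p]; int run = 0;
    while (p >= 0 && ops[p] == op) { ++run; --p; }
    cigar += std::to_string(run); cigar.push_back(op);
  }

  return List::create(_["score"] = best, _["q_off"] = i, _["t_off"] = j,
                      _["q_end"] = b_i, _["t_end"] = b_j,
                      _["cigar"] = cigar, _["ngaps"] = ngaps);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
        default: break; // N etc. unchanged
      }
    }
    out[i] = r;
  }
  return out;
}

static inline bool encode_kmer(const char *s, int k, uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t b;
    switch (s[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: return false;
    }
    code = (code << 2) | b;
  }
  return true;
}

// Exact k-mer seeding: for each query, look up k-mers taken at the start,
// middle and end of the query in an index of all reference k-mers, and
// return the implied (unique, sorted) 0-based query start positions on the
// reference.  Strand handling is the caller's job (pass
// reverse-complemented queries for the minus strand).
// [[Rcpp::export]]
List cpp_seed_hits(CharacterVector queries, std::string ref, int k) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  const int nref = (int)ref.size();
  idx.reserve(nref > k ? nref - k + 1 : 1);
  uint64_t code;
  for (int p = 0; p + k <= nref; ++p) {
    if (encode_kmer(ref.c_str() + p, k, code)) idx[code].push_back(p);
  }
  const int n = queries.size();
  List out(n);
  for (int qi = 0; qi < n; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    const int lq = (int)q.size();
    std::vector<int> starts;
    if (lq >= k) {
      int offs[3] = {0, (lq - k) / 2, lq - k};
      for (int oi = 0; oi < 3; ++oi) {
        int o = offs[oi];
        if (oi > 0 && o == offs[oi - 1]) continue;
        if (!encode_kmer(q.c_str() + o, k, code)) continue;
        auto it = idx.find(code);
        if (it == idx.end()) continue;
        for (int p : it->second) starts.push_back(p - o);
      }
    }
    std::sort(starts.begin(), starts.end());
    starts.erase(std::unique(starts.begin(), starts.end()), starts.end());
    out[qi] = IntegerVector(starts.begin(), starts.end());
  }
  return out;
}
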