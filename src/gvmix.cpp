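#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <climits>
#include <cmath>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline int base_col(char c) {
  int b = base_code(c);
  return (b >= 0) ? b : 4;  // everything unresolved counts as N
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N'; break;
    }
  }
  return r;
}

// ungapped +1/-2 score of read placed at 0-based start on the doubled
// reference (start < L so the window never leaves the buffer for rl <= L)
static int score_at(const std::string& ref2, const std::string& read,
                    int start) {
  int s = 0;
  for (size_t j = 0; j < read.size(); ++j)
    s += (ref2[start + j] == read[j]) ? 1 : -2;
  return s;
}

// Seed-and-extend read mapping against a circular reference.
// Exact k-mer seeds (non-overlapping offsets plus the read tail) propose
// candidate placements; each candidate is scored by full-length ungapped
// extension. Mapping quality is 60 for a unique best placement, 0 for a
// tie, and otherwise scales with the score gap to the runner-up.
// [[Rcpp::export]]
List map_reads_cpp(std::string cons, CharacterVector reads, int k,
                   double min_score_frac) {
  int L = cons.size();
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  std::string ref2 = cons + cons;
  std::unordered_map<uint64_t, std::vector<int> > index;
  uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  uint64_t h = 0;
  int run = 0;
  for (int i = 0; i < L + k - 1 && i < (int)ref2.size(); ++i) {
    int c = base_code(ref2[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    ++run;
    if (run >= k) {
      int pos = i - k + 1;
      if (pos < L) index[h].push_back(pos);
    }
  }

  int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector start(n), mapq(n), score(n);
  CharacterVector strand(n);

  std::vector<int> offsets;
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int rl = fwd.size();
    if (rl < k || rl > L) { mapped[i] = false; continue; }
    std::string rev = revcomp(fwd);
    int min_score = (int)std::ceil(min_score_frac * rl);

    offsets.clear();
    for (int o = 0; o + k <= rl; o += k) offsets.push_back(o);
    if (offsets.empty() || offsets.back() != rl - k)
      offsets.push_back(rl - k);

    int best = INT_MIN, second = INT_MIN, best_start = -1;
    char best_strand = '+';
    for (int s = 0; s < 2; ++s) {
      const std::string& rd = (s == 0) ? fwd : rev;
      std::unordered_set<int> cands;
      for (size_t oi = 0; oi < offsets.size(); ++oi) {
        int o = offsets[oi];
        uint64_t hh = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int c = base_code(rd[o + j]);
          if (c < 0) { ok = false; break; }
          hh = ((hh << 2) | (uint64_t)c) & mask;
        }
        if (!ok) continue;
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
          index.find(hh);
        if (it == index.end()) continue;
        for (size_t pi = 0; pi < it->second.size(); ++pi) {
          int cand = ((it->second[pi] - o) % L + L) % L;
          cands.insert(cand);
        }
      }
      for (std::unordered_set<int>::const_iterator ci = cands.begin();
           ci != cands.end(); ++ci) {
        int sc = score_at(ref2, rd, *ci);
        if (sc > best) {
          second = best;
          best = sc;
          best_start = *ci;
          best_strand = (s == 0) ? '+' : '-';
        } else if (sc > second) {
          second = sc;
        }
      }
    }

    if (best_start < 0 || best < min_score) {
      mapped[i] = false;
      continue;
    }
    mapped[i] = true;
    start[i] = best_start + 1;  // 1-based
    strand[i] = (best_strand == '+') ? "+" : "-";
    score[i] = best;
    if (second == INT_MIN) mapq[i] = 60;
    else if (second == best) mapq[i] = 0;
    else mapq[i] = std::min(60, 6 * (best - second));
  }
  return List::create(_["mapped"] = mapped, _["start"] = start,
                      _["strand"] = strand, _["mapq"] = mapq,
                      _["score"] = score);
}

// Per-position base counting over MAPQ-passing alignment records.
// Records must arrive sorted by pair id; when both mates of a fragment
// cover a position and dedup_mates is true, the base from the mate with
// the higher Phred quality at that position is counted once (ties favour
// the record seen first).
// [[Rcpp::export]]
IntegerMatrix pileup_cpp(IntegerVector pair_id, IntegerVector start,
                         CharacterVector seq, CharacterVector qual,
                         int L, bool dedup_mates) {
  int n = pair_id.size();
  IntegerMatrix counts(L, 5);
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && pair_id[j] == pair_id[i]) ++j;
    if (!dedup_mates || j - i == 1) {
      for (int r = i; r < j; ++r) {
        std::string sq = as<std::string>(seq[r]);
        int s0 = start[r] - 1;
        for (size_t p = 0; p < sq.size(); ++p)
          counts((s0 + (int)p) % L, base_col(sq[p]))++;
      }
    } else {
      std::unordered_map<int, std::pair<char, char> > frag;
      for (int r = i; r < j; ++r) {
        std::string sq = as<std::string>(seq[r]);
        std::string ql = as<std::string>(qual[r]);
        int s0 = start[r] - 1;
        for (size_t p = 0; p < sq.size(); ++p) {
          int pos = (s0 + (int)p) % L;
          char q = (p < ql.size()) ? ql[p] : '!';
          std::unordered_map<int, std::pair<char, char> >::iterator it =
            frag.find(pos);
          if (it == frag.end())
            frag[pos] = std::make_pair(sq[p], q);
          else if (q > it->second.second)
            it->second = std::make_pair(sq[p], q);
        }
      }
      for (std::unordered_map<int, std::pair<char, char> >::const_iterator
             it = frag.begin(); it != frag.end(); ++it)
        counts(it->first, base_col(it->second.first))++;
    }
    i = j;
  }
  return counts;
}
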