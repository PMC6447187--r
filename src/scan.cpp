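#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include "align_common.h"

using namespace Rcpp;

// Seed-and-extend off-target matcher.
//
// For every fragment, exact seed_len-mer matches against each subject strand
// nominate diagonals; around each nominated diagonal a banded DP (band width
// max_gaps on either side) enumerates all alignments that start and end with
// a match column, tracking (gap columns, mismatches) exactly. Every alignment
// passing the acceptance rule is emitted as a candidate; duplicates found
// from different seeds are removed. Collapsing overlapping candidates into
// reported hits happens in R, shared with the brute-force oracle route.
//
// Completeness: an acceptable alignment under thresholds (len >= 18,
// identity > 90, gaps <= 2) of a 19-mer has at most 2 non-match columns,
// so its match columns contain an exact run of >= ceil(17/3) = 7 aligned
// bases on a single diagonal of the alignment; any seed_len <= 7 therefore
// nominates a diagonal within max_gaps of every alignment diagonal.

namespace {

const int NBASE = -1;

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return NBASE;
  }
}

// positions of every seed_len-mer (A/C/G/T only), 2-bit packed
void index_seeds(const std::string &s, int seed_len,
                 std::unordered_map<uint64_t, std::vector<int> > &idx) {
  idx.clear();
  const int L = (int)s.size();
  if (L < seed_len) return;
  const uint64_t mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  uint64_t code = 0;
  int run = 0;  // valid (non-N) bases accumulated
  for (int j = 0; j < L; ++j) {
    int b = base_code(s[j]);
    if (b == NBASE) {
      run = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= seed_len) idx[code].push_back(j - seed_len + 1);
  }
}

struct BandState {
  int M;      // match columns; -1 = unreachable
  int start;  // 0-based subject start of the best path
};

// Banded DP of fragment q against subject s around diagonal d.
// Emits accepted candidates (coordinates on the given strand of s).
void extend_diagonal(const std::string &q, const std::string &s, int d,
                     int min_len, double min_id, int max_gaps, int mm_layers,
                     std::vector<Candidate> &out, int frag, int subj,
                     char strand) {
  const int k = (int)q.size();
  const int L = (int)s.size();
  const int W = 2 * max_gaps + 1;
  const int G = max_gaps + 1;
  const int MM = mm_layers + 1;
  const int S = W * G * MM;
  // rows indexed [band offset][gaps][mismatches]
  std::vector<BandState> prev(S, BandState{-1, 0}), cur(S, BandState{-1, 0});
  std::vector<BandState> row0(S, BandState{-1, 0});

  for (int i = 1; i <= k; ++i) {
    std::fill(cur.begin(), cur.end(), BandState{-1, 0});
    for (int o = 0; o < W; ++o) {
      const int j = i + d - max_gaps + o;
      if (j < 1 || j > L) continue;
      const char a = q[i - 1];
      const char b = s[j - 1];
      const bool eq = (a == b) && (a != 'N');
      for (int g = 0; g < G; ++g) {
        for (int mm = 0; mm < MM; ++mm) {
          const int st = (o * G + g) * MM + mm;
          BandState best = {-1, 0};
          if (eq) {
            const BandState &p = (i >= 2) ? prev[st] : row0[st];
            if (p.M >= 1) best = BandState{p.M + 1, p.start};
            if (g == 0 && mm == 0 && 1 > best.M) best = BandState{1, j - 1};
            // emission: alignment ending in this match column
            if (best.M >= 1 &&
                accept_alignment(best.M, mm, g, min_len, min_id, max_gaps)) {
              Candidate c = {frag, subj, strand, best.start, j,
                             best.M, mm, g};
              out.push_back(c);
            }
          } else if (mm >= 1) {
            const int st2 = (o * G + g) * MM + (mm - 1);
            const BandState &p = (i >= 2) ? prev[st2] : row0[st2];
            if (p.M >= 1) best = BandState{p.M, p.start};
          }
          if (g >= 1) {
            if (o >= 1) {  // query gap: consume subject base, same row
              const int st2 = ((o - 1) * G + (g - 1)) * MM + mm;
              const BandState &p = cur[st2];
              if (p.M >= 1 &&
                  (p.M > best.M || (p.M == best.M && p.start < best.start)))
                best = p;
            }
            if (o + 1 < W && i >= 2) {  // subject gap: consume query base
              const int st2 = ((o + 1) * G + (g - 1)) * MM + mm;
              const BandState &p = prev[st2];
              if (p.M >= 1 &&
                  (p.M > best.M || (p.M == best.M && p.start < best.start)))
                best = p;
            }
          }
          cur[st] = best;
        }
      }
    }
    std::swap(prev, cur);
  }
}

void scan_one_strand(const std::vector<std::string> &frags,
                     const std::string &subj_fwd, char strand,
                     int min_len, double min_id, int max_gaps, int seed_len,
                     int subj_idx, CandSet &dedup) {
  const std::string s = (strand == '+') ? subj_fwd : revcomp(subj_fwd);
  const int L = (int)s.size();
  std::unordered_map<uint64_t, std::vector<int> > idx;
  index_seeds(s, seed_len, idx);
  if (idx.empty()) return;
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;

  for (size_t f = 0; f < frags.size(); ++f) {
    const std::string &q = frags[f];
    const int k = (int)q.size();
    const int mm_layers = max_mismatch_layers(k, min_id);
    std::vector<int> diags;
    uint64_t code = 0;
    int run = 0;
    for (int i = 0; i < k; ++i) {
      int b = base_code(q[i]);
      if (b == NBASE) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= seed_len) {
        const int qoff = i - seed_len + 1;
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            idx.find(code);
        if (it != idx.end()) {
          for (size_t h = 0; h < it->second.size(); ++h)
            diags.push_back(it->second[h] - qoff);
        }
      }
    }
    std::sort(diags.begin(), diags.end());
    diags.erase(std::unique(diags.begin(), diags.end()), diags.end());

    std::vector<Candidate> cands;
    for (size_t di = 0; di < diags.size(); ++di) {
      extend_diagonal(q, s, diags[di], min_len, min_id, max_gaps, mm_layers,
                      cands, (int)f, subj_idx, strand);
    }
    for (size_t c = 0; c < cands.size(); ++c) {
      Candidate cd = cands[c];
      if (strand == '-') {  // map span back to forward-strand coordinates
        const int a = cd.s_start, b2 = cd.s_end;
        cd.s_start = L - b2;
        cd.s_end = L - a;
      }
      insert_candidate(dedup, cd);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_scan_seeded(CharacterVector frag_kmers,
                          CharacterVector subj_seqs,
                          int min_len, double min_id, int max_gaps,
                          int seed_len, bool both_strands) {
  if (seed_len < 1 || seed_len > 31)
    stop("seed_len must be between 1 and 31");
  std::vector<std::string> frags(frag_kmers.size());
  for (int i = 0; i < frag_kmers.size(); ++i)
    frags[i] = as<std::string>(frag_kmers[i]);

  CandSet dedup;
  for (int sj = 0; sj < subj_seqs.size(); ++sj) {
    const std::string subj = as<std::string>(subj_seqs[sj]);
    scan_one_strand(frags, subj, '+', min_len, min_id, max_gaps, seed_len,
                    sj, dedup);
    if (both_strands)
      scan_one_strand(frags, subj, '-', min_len, min_id, max_gaps, seed_len,
                      sj, dedup);
  }

  const int n = (int)dedup.size();
  IntegerVector frag(n), subj(n), s_start(n), s_end(n), matches(n),
      mismatches(n), gaps(n);
  CharacterVector strand(n);
  int i = 0;
  for (CandSet::const_iterator it = dedup.begin(); it != dedup.end();
       ++it, ++i) {
    frag[i] = std::get<0>(*it) + 1;
    subj[i] = std::get<1>(*it) + 1;
    strand[i] = std::string(1, std::get<2>(*it));
    s_start[i] = std::get<3>(*it);
    s_end[i] = std::get<4>(*it);
    matches[i] = std::get<5>(*it);
    mismatches[i] = std::get<6>(*it);
    gaps[i] = std::get<7>(*it);
  }
  return DataFrame::create(
      _["frag"] = frag, _["subj"] = subj, _["strand"] = strand,
      _["subject_start"] = s_start, _["subject_end"] = s_end,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gap_count"] = gaps, _["stringsAsFactors"] = false);
}
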