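#include <Rcpp.h>
#include <algorithm>
#include "align_common.h"

using namespace Rcpp;

// Brute-force off-target oracle.
//
// Unseeded, unbanded dynamic program over every (fragment, subject, strand)
// triple: for each cell (query position i, subject position j) and each
// (gap columns, mismatches) layer it tracks the maximum number of match
// columns over all alignments that start with a match column and end at
// (i, j), emitting every match-ending alignment that passes the acceptance
// rule. Quadratic and exhaustive by construction; used as the independent
// reference for the seeded matcher.

namespace {

struct Cell {
  int M;
  int start;
};

void brute_one_strand(const std::string &q, const std::string &subj_fwd,
                      char strand, int min_len, double min_id, int max_gaps,
                      int frag, int subj_idx, CandSet &out) {
  const std::string s = (strand == '+') ? subj_fwd : revcomp(subj_fwd);
  const int k = (int)q.size();
  const int L = (int)s.size();
  const int G = max_gaps + 1;
  const int MM = max_mismatch_layers(k, min_id) + 1;
  const int S = G * MM;
  std::vector<Cell> prev((size_t)(L + 1) * S, Cell{-1, 0});
  std::vector<Cell> cur((size_t)(L + 1) * S, Cell{-1, 0});

  for (int i = 1; i <= k; ++i) {
    const char a = q[i - 1];
    for (int j = 0; j <= L; ++j) {
      for (int st = 0; st < S; ++st) cur[(size_t)j * S + st].M = -1;
      if (j == 0) continue;
      const char b = s[j - 1];
      const bool eq = (a == b) && (a != 'N');
      for (int g = 0; g < G; ++g) {
        for (int mm = 0; mm < MM; ++mm) {
          const size_t st = (size_t)j * S + g * MM + mm;
          Cell best = {-1, 0};
          if (eq) {
            const Cell &p = prev[(size_t)(j - 1) * S + g * MM + mm];
            if (p.M >= 1) best = Cell{p.M + 1, p.start};
            if (g == 0 && mm == 0 && best.M < 1) best = Cell{1, j - 1};
            if (best.M >= 1 &&
                accept_alignment(best.M, mm, g, min_len, min_id, max_gaps)) {
              Candidate c;
              c.frag = frag;
              c.subj = subj_idx;
              c.strand = strand;
              c.s_start = best.start;
              c.s_end = j;
              c.matches = best.M;
              c.mismatches = mm;
              c.gaps = g;
              if (strand == '-') {
                c.s_start = L - j;
                c.s_end = L - best.start;
              }
              insert_candidate(out, c);
            }
          } else if (mm >= 1) {
            const Cell &p = prev[(size_t)(j - 1) * S + g * MM + (mm - 1)];
            if (p.M >= 1) best = Cell{p.M, p.start};
          }
          if (g >= 1) {
            const Cell &pq = cur[(size_t)(j - 1) * S + (g - 1) * MM + mm];
            if (pq.M >= 1 &&
                (pq.M > best.M || (pq.M == best.M && pq.start < best.start)))
              best = pq;
            const Cell &ps = prev[(size_t)j * S + (g - 1) * MM + mm];
            if (ps.M >= 1 &&
                (ps.M > best.M || (ps.M == best.M && ps.start < best.start)))
              best = ps;
          }
          cur[st] = best;
        }
      }
    }
    std::swap(prev, cur);
  }
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_scan_brute(CharacterVector frag_kmers,
                         CharacterVector subj_seqs,
                         int min_len, double min_id, int max_gaps,
                         bool both_strands) {
  CandSet out;
  for (int sj = 0; sj < subj_seqs.size(); ++sj) {
    const std::string subj = as<std::string>(subj_seqs[sj]);
    for (int f = 0; f < frag_kmers.size(); ++f) {
      const std::string q = as<std::string>(frag_kmers[f]);
      brute_one_strand(q, subj, '+', min_len, min_id, max_gaps, f, sj, out);
      if (both_strands)
        brute_one_strand(q, subj, '-', min_len, min_id, max_gaps, f, sj, out);
    }
  }
  const int n = (int)out.size();
  IntegerVector frag(n), subj(n), s_start(n), s_end(n), matches(n),
      mismatches(n), gaps(n);
  CharacterVector strand(n);
  int i = 0;
  for (CandSet::const_iterator it = out.begin(); it != out.end(); ++it, ++i) {
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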