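#ifndef DSTILE_ALIGN_COMMON_H
#define DSTILE_ALIGN_COMMON_H

#include <string>
#include <vector>
#include <set>
#include <tuple>

// Shared plumbing for the two off-target search routes (seeded matcher and
// brute-force DP oracle). Only trivially-correct helpers live here; the
// search algorithms themselves are deliberately independent.

struct Candidate {
  int frag;     // 0-based index into the fragment list
  int subj;     // 0-based index into the subject list
  char strand;  // '+' or '-'
  int s_start;  // 0-based half-open span on the FORWARD strand of the subject
  int s_end;
  int matches;
  int mismatches;
  int gaps;     // gapped columns
};

inline char complement_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

inline std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complement_base(r[i]);
  return r;
}

// Alignment columns must be >= min_len, identity strictly > min_id (percent),
// gapped columns <= max_gaps. Identity counts gap columns in the denominator
// (BLAST pident convention); N never counts as a match.
inline bool accept_alignment(int matches, int mismatches, int gaps,
                             int min_len, double min_id, int max_gaps) {
  const int m = matches + mismatches + gaps;
  if (m < min_len) return false;
  if (gaps > max_gaps) return false;
  return 100.0 * matches > min_id * m;
}

// Most mismatches any acceptable alignment of a k-mer query can carry:
// matches <= k - mm (both consume query), so identity <= (k-mm)/(k-mm+mm).
inline int max_mismatch_layers(int k, double min_id) {
  int mm = 0;
  while (mm + 1 < k && 100.0 * (k - (mm + 1)) > min_id * k) ++mm;
  return mm;
}

typedef std::set<std::tuple<int, int, char, int, int, int, int, int> > CandSet;

inline void insert_candidate(CandSet &set, const Candidate &c) {
  set.insert(std::make_tuple(c.frag, c.subj, c.strand, c.s_start, c.s_end,
                             c.matches, c.mismatches, c.gaps));
}

#endif
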