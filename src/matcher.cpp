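// k-mer-seeded ungapped read matcher.
//
// Candidate (reference, offset) pairs are proposed by exact shared k-mers;
// each candidate is then scored as a single ungapped alignment over the full
// read/reference overlap at that offset.  Acceptance and tie-breaking are
// fully specified so results are identical across platforms and input
// orderings: highest identity wins, ties broken by longer aligned span, then
// by lexicographically smallest reference id.  Identity comparisons are done
// with exact integer cross-multiplication, never with floating ratios.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

struct Hit {
  int ref;      // 0-based reference index, -1 = none
  int matches;  // identical positions in the aligned span
  int span;     // aligned span length
  int strand;   // 0 = forward, 1 = reverse complement of the read
  Hit() : ref(-1), matches(0), span(0), strand(0) {}
};

// true if (m1, s1) is a strictly better hit than (m2, s2) on ref names a/b
static inline bool better(long long m1, long long s1, const std::string &a,
                          long long m2, long long s2, const std::string &b) {
  long long lhs = m1 * s2, rhs = m2 * s1;  // identity comparison
  if (lhs != rhs) return lhs > rhs;
  if (s1 != s2) return s1 > s2;
  return a < b;
}

typedef std::unordered_map<std::uint64_t, std::vector<std::uint64_t>> KmerIndex;

static void add_ref_kmers(KmerIndex &index, const std::vector<int8_t> &seq,
                          int ref_idx, int k) {
  const int n = (int)seq.size();
  std::uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    if (seq[i] < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (std::uint64_t)seq[i]) & mask;
    if (++run >= k) {
      int pos = i - k + 1;
      index[kmer].push_back(((std::uint64_t)(std::uint32_t)ref_idx << 32) |
                            (std::uint32_t)pos);
    }
  }
}

static std::vector<int8_t> encode(const char *s) {
  std::vector<int8_t> v;
  for (; *s; ++s) v.push_back((int8_t)base2bit(*s));
  return v;
}

// Scan one encoded read orientation against the index, updating `best`.
static void scan_orientation(const std::vector<int8_t> &read, int strand,
                             const KmerIndex &index,
                             const std::vector<std::vector<int8_t>> &refs,
                             const std::vector<std::string> &ref_ids,
                             const NumericVector &min_ident,
                             const NumericVector &min_frac, int k, Hit &best) {
  const int rl = (int)read.size();
  if (rl < k) return;
  std::uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  std::unordered_set<std::int64_t> seen;
  for (int i = 0; i < rl; ++i) {
    if (read[i] < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (std::uint64_t)read[i]) & mask;
    if (++run < k) continue;
    KmerIndex::const_iterator it = index.find(kmer);
    if (it == index.end()) continue;
    int p = i - k + 1;  // k-mer start in read
    for (std::uint64_t packed : it->second) {
      int r = (int)(packed >> 32);
      int q = (int)(packed & 0xffffffffULL);  // k-mer start in reference
      int off = q - p;  // read position j aligns reference position j + off
      std::int64_t key = ((std::int64_t)r << 24) ^ (std::int64_t)(off + rl);
      if (!seen.insert(key).second) continue;
      const std::vector<int8_t> &ref = refs[r];
      const int L = (int)ref.size();
      int j0 = off < 0 ? -off : 0;
      int j1 = (L - off) < rl ? (L - off) : rl;
      int span = j1 - j0;
      if (span <= 0) continue;
      if ((double)span < min_frac[r] * (double)rl) continue;
      int m = 0;
      for (int j = j0; j < j1; ++j)
        if (read[j] >= 0 && read[j] == ref[j + off]) ++m;
      if ((double)m * 100.0 < min_ident[r] * (double)span) continue;
      // strict improvement required, so on exact ties (identity, span,
      // reference id) the earlier-scanned forward orientation is kept
      if (best.ref < 0 ||
          better(m, span, ref_ids[r], best.matches, best.span,
                 ref_ids[best.ref])) {
        best.ref = r; best.matches = m; best.span = span; best.strand = strand;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_match_reads(CharacterVector reads, CharacterVector refs,
                          NumericVector min_ident, NumericVector min_frac,
                          int k, bool both_strands) {
  const int nref = refs.size(), nread = reads.size();
  if (nref == 0) stop("empty reference set");
  if (k < 4 || k > 32) stop("k must be in [4, 32]");
  if (min_ident.size() != nref || min_frac.size() != nref)
    stop("threshold vectors must have one entry per reference");

  std::vector<std::vector<int8_t>> ref_seqs(nref);
  std::vector<std::string> ref_ids(nref);
  KmerIndex index;
  CharacterVector ref_names = refs.attr("names");
  for (int r = 0; r < nref; ++r) {
    ref_seqs[r] = encode(CHAR(STRING_ELT(refs, r)));
    ref_ids[r] = as<std::string>(ref_names[r]);
    add_ref_kmers(index, ref_seqs[r], r, k);
  }

  IntegerVector out_ref(nread), out_matches(nread), out_span(nread),
      out_strand(nread);
  for (int i = 0; i < nread; ++i) {
    std::vector<int8_t> fwd = encode(CHAR(STRING_ELT(reads, i)));
    if ((int)fwd.size() < k)
      stop("k (%d) larger than read length (%d) at read %d", k,
           (int)fwd.size(), i + 1);
    Hit best;
    scan_orientation(fwd, 0, index, ref_seqs, ref_ids, min_ident, min_frac, k,
                     best);
    if (both_strands) {
      std::vector<int8_t> rev(fwd.size());
      for (size_t j = 0; j < fwd.size(); ++j) {
        int8_t b = fwd[fwd.size() - 1 - j];
        rev[j] = b < 0 ? b : (int8_t)(3 - b);
      }
      scan_orientation(rev, 1, index, ref_seqs, ref_ids, min_ident, min_frac,
                       k, best);
    }
    out_ref[i] = best.ref + 1;  // 0 = no hit
    out_matches[i] = best.matches;
    out_span[i] = best.span;
    out_strand[i] = best.strand;
  }
  return DataFrame::create(_["ref"] = out_ref, _["matches"] = out_matches,
                           _["span"] = out_span, _["strand"] = out_strand);
}
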