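#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Canonical form: lexicographic min of the k-mer and its reverse complement,
// so a k-mer and its reverse complement share one hash key. Palindromes
// (own reverse complement) collapse to a single key and are counted once
// per occurrence.
static std::string canonical_kmer(const char* s, int k) {
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) rc[k - 1 - i] = comp_base(s[i]);
  std::string fwd(s, k);
  return (rc < fwd) ? rc : fwd;
}

//' Per-start-position k-mer occurrence counts over a set of sequences
//'
//' Counts, for every k-mer start position in every sequence, how many times
//' that k-mer occurs over both strands of the whole sequence set (forward
//' occurrences plus forward occurrences of its reverse complement). Positions
//' whose k-mer window contains a non-ACGT character, and the trailing k-1
//' positions with no full window, get NA.
//'
//' @param seqs character vector of uppercase DNA sequences
//' @param k k-mer length
//' @return list of integer vectors, one per sequence, length = nchar(seq)
//' @keywords internal
// [[Rcpp::export]]
List kmer_occurrence_counts(CharacterVector seqs, int k) {
  if (k < 1) stop("k must be >= 1");
  int nseq = seqs.size();
  std::vector<std::string> sv(nseq);
  for (int i = 0; i < nseq; ++i) sv[i] = as<std::string>(seqs[i]);

  std::unordered_map<std::string, int> counts;
  size_t total = 0;
  for (int i = 0; i < nseq; ++i) total += sv[i].size();
  counts.reserve(total);

  // pass 1: count canonical k-mers over all valid windows
  for (int i = 0; i < nseq; ++i) {
    const std::string& s = sv[i];
    long n = (long)s.size();
    if (n < k) continue;
    long bad_until = -1; // last index (exclusive) invalidated by a non-ACGT base
    for (long j = 0; j + k <= n; ++j) {
      bool ok = true;
      if (j == 0) {
        for (int t = 0; t < k; ++t) if (!valid_base(s[j + t])) { ok = false; bad_until = j + t; }
      } else {
        if (!valid_base(s[j + k - 1])) bad_until = j + k - 1;
        if (bad_until >= j) ok = false;
      }
      if (!ok) continue;
      counts[canonical_kmer(s.c_str() + j, k)] += 1;
    }
  }

  // pass 2: look up each position's count
  List out(nseq);
  for (int i = 0; i < nseq; ++i) {
    const std::string& s = sv[i];
    long n = (long)s.size();
    IntegerVector v(n, NA_INTEGER);
    long bad_until = -1;
    for (long j = 0; j + k <= n; ++j) {
      bool ok = true;
      if (j == 0) {
        for (int t = 0; t < k; ++t) if (!valid_base(s[j + t])) { ok = false; bad_until = j + t; }
      } else {
        if (!valid_base(s[j + k - 1])) bad_until = j + k - 1;
        if (bad_until >= j) ok = false;
      }
      if (!ok) continue;
      v[j] = counts[canonical_kmer(s.c_str() + j, k)];
    }
    out[i] = v;
  }
  if (!Rf_isNull(seqs.names())) out.names() = seqs.names();
  return out;
}
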