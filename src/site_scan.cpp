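// Exact enumeration of Cas9 target sites and bounded-Hamming retrieval.
//
// Two independent search paths are provided on purpose:
//  - cpp_scan_sites + cpp_trie_query: one pass over the genome collects every
//    PAM-adjacent protospacer; queries run a depth-first bounded-mismatch
//    traversal over the sorted key set (an implicit prefix tree).
//  - cpp_brute_scan: a per-guide sliding-window scan that re-reads the genome
//    and counts mismatches directly. It shares no state with the index and
//    serves as the exhaustiveness oracle.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstring>
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

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

// IUPAC code -> 4-bit mask over (A,C,G,T)
static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

struct PamSet {
  // masks[p][pos] = allowed-base bitmask for pattern p at PAM position pos
  std::vector<std::array<int, 3> > masks;

  explicit PamSet(const CharacterVector& pams) {
    for (int i = 0; i < pams.size(); ++i) {
      std::string p = as<std::string>(pams[i]);
      if (p.size() != 3) stop("PAM patterns must be 3-mers, got '%s'", p.c_str());
      std::array<int, 3> m;
      for (int j = 0; j < 3; ++j) {
        m[j] = iupac_mask(p[j]);
        if (m[j] == 0) stop("invalid IUPAC code '%c' in PAM '%s'", p[j], p.c_str());
      }
      masks.push_back(m);
    }
  }

  // codes must be valid base codes (0..3)
  inline bool match(int c0, int c1, int c2) const {
    for (size_t i = 0; i < masks.size(); ++i) {
      if ((masks[i][0] & (1 << c0)) && (masks[i][1] & (1 << c1)) &&
          (masks[i][2] & (1 << c2)))
        return true;
    }
    return false;
  }
};

// Scan every sequence on both strands for k-mer protospacers followed by a
// PAM match. Protospacers are reported 5'->3' on the cutting strand; start is
// the leftmost 0-based coordinate of the protospacer on the + strand.
// [[Rcpp::export]]
DataFrame cpp_scan_sites(CharacterVector seqs, int k, CharacterVector pams) {
  PamSet pam(pams);
  std::vector<int> out_chrom, out_start;
  std::vector<std::string> out_proto, out_pam;
  std::vector<int> out_strand;  // 1 = '+', 0 = '-'

  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    const long L = (long)s.size();
    if (L < k + 3) continue;
    std::vector<signed char> code(L);
    for (long i = 0; i < L; ++i) code[i] = (signed char)base_code(s[i]);
    // prefix count of invalid characters for O(1) window validity
    std::vector<int> bad(L + 1, 0);
    for (long i = 0; i < L; ++i) bad[i + 1] = bad[i] + (code[i] < 0);

    // + strand: protospacer [p, p+k), PAM [p+k, p+k+3)
    for (long p = 0; p + k + 3 <= L; ++p) {
      if (bad[p + k + 3] - bad[p] > 0) continue;
      if (!pam.match(code[p + k], code[p + k + 1], code[p + k + 2])) continue;
      out_chrom.push_back(si + 1);
      out_start.push_back((int)p);
      out_strand.push_back(1);
      out_proto.push_back(s.substr(p, k));
      out_pam.push_back(s.substr(p + k, 3));
    }
    // - strand: protospacer occupies [q, q+k) with PAM at [q-3, q) on the +
    // strand; cutting-strand sequences are reverse complements.
    for (long q = 3; q + k <= L; ++q) {
      if (bad[q + k] - bad[q - 3] > 0) continue;
      int c0 = 3 - code[q - 1], c1 = 3 - code[q - 2], c2 = 3 - code[q - 3];
      if (!pam.match(c0, c1, c2)) continue;
      std::string proto(k, 'N'), pm(3, 'N');
      for (int i = 0; i < k; ++i) proto[i] = comp_base(s[q + k - 1 - i]);
      pm[0] = comp_base(s[q - 1]); pm[1] = comp_base(s[q - 2]); pm[2] = comp_base(s[q - 3]);
      out_chrom.push_back(si + 1);
      out_start.push_back((int)q);
      out_strand.push_back(0);
      out_proto.push_back(proto);
      out_pam.push_back(pm);
    }
  }

  return DataFrame::create(_["chrom_idx"] = out_chrom, _["start"] = out_start,
                           _["strand_plus"] = out_strand,
                           _["protospacer"] = out_proto, _["pam"] = out_pam,
                           _["stringsAsFactors"] = false);
}

namespace {

struct TrieQuery {
  const std::vector<signed char>* codes;  // flattened n x k site codes
  int k;
  int max_d;
  const signed char* guide;  // k codes
  std::vector<int>* hit_idx;
  std::vector<int>* hit_dist;

  // [lo, hi): range of (sorted) sites sharing the first `depth` bases
  void dfs(long lo, long hi, int depth, int mm) {
    if (lo >= hi) return;
    if (depth == k) {
      for (long i = lo; i < hi; ++i) {
        hit_idx->push_back((int)i);
        hit_dist->push_back(mm);
      }
      return;
    }
    const std::vector<signed char>& cd = *codes;
    long pos = lo;
    while (pos < hi) {
      signed char b = cd[pos * k + depth];
      // advance to end of this base's sub-range (keys are sorted, so equal
      // prefixes are contiguous); binary search keeps large ranges cheap
      long lo2 = pos, hi2 = hi;
      while (lo2 < hi2) {
        long mid = (lo2 + hi2) / 2;
        if (cd[mid * k + depth] <= b) lo2 = mid + 1; else hi2 = mid;
      }
      int mm2 = mm + (b == guide[depth] ? 0 : 1);
      if (mm2 <= max_d) dfs(pos, lo2, depth + 1, mm2);
      pos = lo2;
    }
  }
};

}  // namespace

// Bounded-mismatch retrieval over the sorted protospacer keys of an index.
// `protospacers` must be lexicographically sorted. Returns one row per
// (guide, site) match with the Hamming distance.
// [[Rcpp::export]]
DataFrame cpp_trie_query(CharacterVector protospacers, CharacterVector guides,
                         int max_distance) {
  const long n = protospacers.size();
  int k = n > 0 ? (int)std::strlen(CHAR(STRING_ELT(protospacers, 0))) : 0;
  std::vector<signed char> codes((size_t)n * k);
  for (long i = 0; i < n; ++i) {
    const char* p = CHAR(STRING_ELT(protospacers, i));
    if ((int)std::strlen(p) != k) stop("index protospacers have unequal lengths");
    for (int j = 0; j < k; ++j) {
      int c = base_code(p[j]);
      if (c < 0) stop("non-ACGT character in index protospacer %d", (int)(i + 1));
      codes[(size_t)i * k + j] = (signed char)c;
    }
  }

  std::vector<int> res_guide, res_site, res_dist;
  for (int g = 0; g < guides.size(); ++g) {
    std::string gs = as<std::string>(guides[g]);
    if ((int)gs.size() != k && n > 0)
      stop("guide %d has length %d but index k = %d", g + 1, (int)gs.size(), k);
    std::vector<signed char> gc(gs.size());
    for (size_t j = 0; j < gs.size(); ++j) {
      int c = base_code(gs[j]);
      if (c < 0) stop("non-ACGT character in guide %d", g + 1);
      gc[j] = (signed char)c;
    }
    if (n == 0) continue;
    std::vector<int> hi, hd;
    TrieQuery q{&codes, k, max_distance, gc.data(), &hi, &hd};
    q.dfs(0, n, 0, 0);
    for (size_t t = 0; t < hi.size(); ++t) {
      res_guide.push_back(g + 1);
      res_site.push_back(hi[t] + 1);
      res_dist.push_back(hd[t]);
    }
  }
  return DataFrame::create(_["guide_idx"] = res_guide, _["site_idx"] = res_site,
                           _["distance"] = res_dist);
}

// Independent oracle: per-guide sliding-window scan over both strands with a
// direct mismatch count. Deliberately shares nothing with the trie path.
// [[Rcpp::export]]
DataFrame cpp_brute_scan(CharacterVector seqs, CharacterVector guides, int k,
                         int max_distance, CharacterVector pams) {
  PamSet pam(pams);
  std::vector<int> out_guide, out_chrom, out_start, out_strand, out_dist;
  std::vector<std::string> out_proto, out_pam;

  std::vector<std::string> genome(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) genome[i] = as<std::string>(seqs[i]);

  for (int g = 0; g < guides.size(); ++g) {
    std::string gs = as<std::string>(guides[g]);
    if ((int)gs.size() != k) stop("guide %d length != k", g + 1);
    for (size_t j = 0; j < gs.size(); ++j)
      if (base_code(gs[j]) < 0) stop("non-ACGT character in guide %d", g + 1);

    for (size_t si = 0; si < genome.size(); ++si) {
      const std::string& s = genome[si];
      const long L = (long)s.size();
      // + strand
      for (long p = 0; p + k + 3 <= L; ++p) {
        int c0 = base_code(s[p + k]), c1 = base_code(s[p + k + 1]),
            c2 = base_code(s[p + k + 2]);
        if (c0 < 0 || c1 < 0 || c2 < 0 || !pam.match(c0, c1, c2)) continue;
        int mm = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          char c = s[p + j];
          if (base_code(c) < 0) { ok = false; break; }
          if (c != gs[j] && ++mm > max_distance) { ok = false; break; }
        }
        if (!ok) continue;
        out_guide.push_back(g + 1);
        out_chrom.push_back((int)si + 1);
        out_start.push_back((int)p);
        out_strand.push_back(1);
        out_dist.push_back(mm);
        out_proto.push_back(s.substr(p, k));
        out_pam.push_back(s.substr(p + k, 3));
      }
      // - strand: compare guide against the reverse complement of [q, q+k)
      for (long q = 3; q + k <= L; ++q) {
        int b0 = base_code(s[q - 1]), b1 = base_code(s[q - 2]), b2 = base_code(s[q - 3]);
        if (b0 < 0 || b1 < 0 || b2 < 0) continue;
        if (!pam.match(3 - b0, 3 - b1, 3 - b2)) continue;
        int mm = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          char c = s[q + k - 1 - j];
          if (base_code(c) < 0) { ok = false; break; }
          if (comp_base(c) != gs[j] && ++mm > max_distance) { ok = false; break; }
        }
        if (!ok) continue;
        std::string proto(k, 'N'), pm(3, 'N');
        for (int j = 0; j < k; ++j) proto[j] = comp_base(s[q + k - 1 - j]);
        pm[0] = comp_base(s[q - 1]); pm[1] = comp_base(s[q - 2]); pm[2] = comp_base(s[q - 3]);
        out_guide.push_back(g + 1);
        out_chrom.push_back((int)si + 1);
        out_start.push_back((int)q);
        out_strand.push_back(0);
        out_dist.push_back(mm);
        out_proto.push_back(proto);
        out_pam.push_back(pm);
      }
    }
  }
  return DataFrame::create(_["guide_idx"] = out_guide, _["chrom_idx"] = out_chrom,
                           _["start"] = out_start, _["strand_plus"] = out_strand,
                           _["protospacer"] = out_proto, _["pam"] = out_pam,
                           _["distance"] = out_dist, _["stringsAsFactors"] = false);
}
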