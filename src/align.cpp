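// Ungapped short-read alignment against an allele catalogue:
// 2-bit k-mer index, pigeonhole seeding, full-length Hamming verification.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N or anything else: not indexable
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// encode k-mer; false if it contains a non-ACGT character
static bool encode_kmer(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

struct KIndex {
  int k;
  std::vector<std::string> seqs;
  // k-mer -> (allele index, 0-based position)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > map;
};

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// mismatch count of read r (length w) against subject at offset off,
// early exit once count exceeds cap; N on either side is a mismatch
static inline int mm_count(const std::string &sub, const char *r, int w,
                           int off, int cap) {
  int mm = 0;
  const char *s = sub.data() + off;
  for (int i = 0; i < w; ++i) {
    char a = r[i], b = s[i];
    if (a != b || !valid_base(a)) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  KIndex *idx = new KIndex();
  idx->k = k;
  idx->seqs.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) {
      delete idx;
      stop("k (%d) exceeds the length of allele %d (%d nt)", k, (int)i + 1,
           (int)s.size());
    }
    idx->seqs.push_back(s);
  }
  for (size_t a = 0; a < idx->seqs.size(); ++a) {
    const std::string &s = idx->seqs[a];
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t key;
      if (encode_kmer(s.data() + p, k, key))
        idx->map[key].push_back(std::make_pair((int)a, p));
    }
  }
  XPtr<KIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
IntegerMatrix cpp_index_lookup(SEXP xp_, std::string kmer) {
  XPtr<KIndex> xp(xp_);
  uint64_t key;
  if ((int)kmer.size() != xp->k)
    stop("query length (%d) differs from index k (%d)", (int)kmer.size(),
         xp->k);
  if (!encode_kmer(kmer.data(), xp->k, key))
    return IntegerMatrix(0, 2);
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::iterator
      it = xp->map.find(key);
  if (it == xp->map.end()) return IntegerMatrix(0, 2);
  IntegerMatrix out(it->second.size(), 2);
  for (size_t i = 0; i < it->second.size(); ++i) {
    out(i, 0) = it->second[i].first + 1;  // 1-based allele index for R
    out(i, 1) = it->second[i].second;     // 0-based position
  }
  return out;
}

// [[Rcpp::export]]
double cpp_index_nkeys(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  return (double)xp->map.size();
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  return xp->k;
}

struct Hit {
  int allele;   // 0-based
  int offset;   // 0-based
  int orient;   // 0 forward, 1 reverse complement
  int mm;
};

static void align_one(const KIndex *idx, const std::string &read, int maxmm,
                      std::vector<Hit> &hits) {
  int w = (int)read.size();
  int k = idx->k;
  int nseed = maxmm + 1;
  for (int orient = 0; orient < 2; ++orient) {
    std::string ro = orient == 0 ? read : revcomp_str(read);
    std::vector<std::pair<int, int> > cand;  // (allele, offset)
    if (w >= nseed * k) {
      // pigeonhole: one of maxmm+1 disjoint seeds must be exact
      for (int j = 0; j < nseed; ++j) {
        int s = j * k;
        uint64_t key;
        if (!encode_kmer(ro.data() + s, k, key)) continue;
        std::unordered_map<uint64_t,
                           std::vector<std::pair<int, int> > >::const_iterator
            it = idx->map.find(key);
        if (it == idx->map.end()) continue;
        for (size_t m = 0; m < it->second.size(); ++m) {
          int a = it->second[m].first;
          int off = it->second[m].second - s;
          if (off >= 0 && off + w <= (int)idx->seqs[a].size())
            cand.push_back(std::make_pair(a, off));
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    } else {
      // read too short for seeding: exhaustive scan
      for (size_t a = 0; a < idx->seqs.size(); ++a)
        for (int off = 0; off + w <= (int)idx->seqs[a].size(); ++off)
          cand.push_back(std::make_pair((int)a, off));
    }
    for (size_t c = 0; c < cand.size(); ++c) {
      int a = cand[c].first, off = cand[c].second;
      int mm = mm_count(idx->seqs[a], ro.data(), w, off, maxmm);
      if (mm <= maxmm) {
        Hit h;
        h.allele = a;
        h.offset = off;
        h.orient = orient;
        h.mm = mm;
        hits.push_back(h);
      }
    }
  }
}

// Align a batch of reads. Returns parallel vectors (read index 1-based,
// allele index 1-based, offset 0-based, orient 0/1, mismatches).
// [[Rcpp::export]]
List cpp_align_batch(SEXP xp_, CharacterVector reads, int maxmm,
                     bool best_only) {
  XPtr<KIndex> xp(xp_);
  std::vector<int> v_read, v_allele, v_off, v_orient, v_mm;
  std::vector<Hit> hits;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    hits.clear();
    std::string read = as<std::string>(reads[i]);
    align_one(xp.get(), read, maxmm, hits);
    if (hits.empty()) continue;
    int keepmin = 0;
    if (best_only) {
      keepmin = hits[0].mm;
      for (size_t h = 1; h < hits.size(); ++h)
        if (hits[h].mm < keepmin) keepmin = hits[h].mm;
    }
    for (size_t h = 0; h < hits.size(); ++h) {
      if (best_only && hits[h].mm != keepmin) continue;
      v_read.push_back((int)i + 1);
      v_allele.push_back(hits[h].allele + 1);
      v_off.push_back(hits[h].offset);
      v_orient.push_back(hits[h].orient);
      v_mm.push_back(hits[h].mm);
    }
  }
  return List::create(_["read"] = wrap(v_read), _["allele"] = wrap(v_allele),
                      _["offset"] = wrap(v_off), _["orient"] = wrap(v_orient),
                      _["mismatches"] = wrap(v_mm));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}

// Positions (0-based, subject coordinates) and read bases where an oriented
// read placed at `offset` differs from the subject.
// [[Rcpp::export]]
List cpp_mismatch_positions(std::string read, std::string subject,
                            int offset) {
  std::vector<int> pos;
  std::vector<std::string> alt;
  std::vector<std::string> ref;
  if (offset < 0 || offset + (int)read.size() > (int)subject.size())
    stop("read placement out of subject bounds");
  for (size_t i = 0; i < read.size(); ++i) {
    char a = read[i], b = subject[offset + i];
    if (a != b || !valid_base(a)) {
      pos.push_back(offset + (int)i);
      alt.push_back(std::string(1, a));
      ref.push_back(std::string(1, b));
    }
  }
  return List::create(_["position"] = wrap(pos), _["ref"] = wrap(ref),
                      _["alt"] = wrap(alt));
}
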