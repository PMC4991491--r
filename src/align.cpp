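// Ungapped seed-and-extend aligner over a concatenated two-species
// reference.  A k-mer hash index (forward strand of every chromosome)
// seeds candidate loci; each candidate is verified by full-length
// comparison of both mates in a proper forward/reverse-complement pair
// orientation.  A pair is assigned to the species of its single best
// valid locus; ties on total mismatch count across >= 2 distinct loci
// are ambiguous and dropped, mirroring unique-mapping filters.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

struct SeedIndex {
  int k;
  std::vector<std::string> chrom_names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> table;
};

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base2code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: break;
    }
  }
  return r;
}

// [[Rcpp::export(name = ".build_seed_index_cpp")]]
SEXP build_seed_index_cpp(CharacterVector chrom_names, CharacterVector seqs,
                          int k) {
  if (k < 11 || k > 31) stop("seed length k must be between 11 and 31");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  for (int i = 0; i < chrom_names.size(); ++i) {
    idx->chrom_names.push_back(as<std::string>(chrom_names[i]));
    idx->seqs.push_back(as<std::string>(seqs[i]));
  }
  for (size_t ci = 0; ci < idx->seqs.size(); ++ci) {
    const std::string& s = idx->seqs[ci];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t key;
      if (encode_kmer(s, p, k, key))
        idx->table[key].emplace_back((int32_t)ci, (int32_t)p);
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".index_stats_cpp")]]
List index_stats_cpp(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  size_t npos = 0;
  for (auto& kv : idx->table) npos += kv.second.size();
  return List::create(Named("k") = idx->k,
                      Named("n_kmers") = (double)idx->table.size(),
                      Named("n_positions") = (double)npos,
                      Named("chrom_names") = wrap(idx->chrom_names));
}

// [[Rcpp::export(name = ".index_kmer_hits_cpp")]]
List index_kmer_hits_cpp(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  uint64_t key;
  std::vector<int> chrom; std::vector<int> pos;
  if ((int)kmer.size() == idx->k && encode_kmer(kmer, 0, idx->k, key)) {
    auto it = idx->table.find(key);
    if (it != idx->table.end())
      for (auto& h : it->second) { chrom.push_back(h.first + 1); pos.push_back(h.second + 1); }
  }
  return List::create(Named("chrom") = wrap(chrom), Named("pos") = wrap(pos));
}

struct MateHit { int32_t chrom; int32_t start; int mm; bool fwd; };

// candidate single-mate alignments with mismatch count <= cap
static void mate_candidates(const SeedIndex& idx, const std::string& read,
                            int cap, std::vector<MateHit>& out) {
  const int k = idx.k;
  const int L = (int)read.size();
  if (L < k) return;
  for (int ori = 0; ori < 2; ++ori) {
    const std::string r = ori == 0 ? read : revcomp(read);
    // cap+1 evenly spaced seeds: with <= cap mismatches one seed is clean
    int nseed = cap + 1;
    std::vector<int> offs;
    for (int i = 0; i < nseed; ++i) {
      int o = (nseed == 1) ? 0 : (int)std::lround((double)i * (L - k) / (nseed - 1));
      if (offs.empty() || o != offs.back()) offs.push_back(o);
    }
    std::vector<std::pair<int32_t, int32_t>> seen;
    for (int o : offs) {
      uint64_t key;
      if (!encode_kmer(r, o, k, key)) continue;
      auto it = idx.table.find(key);
      if (it == idx.table.end()) continue;
      for (auto& h : it->second) {
        int32_t ci = h.first;
        int64_t start = (int64_t)h.second - o;
        const std::string& s = idx.seqs[ci];
        if (start < 0 || start + L > (int64_t)s.size()) continue;
        std::pair<int32_t, int32_t> locus(ci, (int32_t)start);
        bool dup = false;
        for (auto& sn : seen) if (sn == locus) { dup = true; break; }
        if (dup) continue;
        seen.push_back(locus);
        int mm = 0;
        for (int i = 0; i < L && mm <= cap; ++i)
          if (s[start + i] != r[i]) ++mm;
        if (mm <= cap) out.push_back({ci, (int32_t)start, mm, ori == 0});
      }
    }
  }
}

// [[Rcpp::export(name = ".assign_pairs_cpp")]]
DataFrame assign_pairs_cpp(SEXP xp, CharacterVector mate1, CharacterVector mate2,
                           int max_mismatch, double max_mm_ratio,
                           int max_fragment) {
  XPtr<SeedIndex> idx(xp);
  int n = mate1.size();
  IntegerVector call(n);          // 0 unmapped, 1 mapped, 2 ambiguous
  IntegerVector chrom(n, NA_INTEGER);
  IntegerVector start(n, NA_INTEGER), end(n, NA_INTEGER);
  IntegerVector mm1v(n, NA_INTEGER), mm2v(n, NA_INTEGER);
  IntegerVector s1(n, NA_INTEGER), e1(n, NA_INTEGER);
  IntegerVector s2(n, NA_INTEGER), e2(n, NA_INTEGER);
  LogicalVector short_mate(n, false);

  for (int i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(mate1[i]);
    std::string r2 = as<std::string>(mate2[i]);
    int L1 = (int)r1.size(), L2 = (int)r2.size();
    if (L1 < idx->k || L2 < idx->k) { call[i] = 0; short_mate[i] = true; continue; }
    std::vector<MateHit> h1, h2;
    mate_candidates(*idx, r1, max_mismatch, h1);
    mate_candidates(*idx, r2, max_mismatch, h2);

    // pair mates: same chromosome, opposite orientation, fragment span bound
    int best = INT_MAX, nbest = 0;
    MateHit b1{0, 0, 0, true}, b2{0, 0, 0, true};
    for (auto& a : h1) {
      for (auto& b : h2) {
        if (a.chrom != b.chrom || a.fwd == b.fwd) continue;
        const MateHit& fw = a.fwd ? a : b;
        const MateHit& rv = a.fwd ? b : a;
        int fwL = a.fwd ? L1 : L2, rvL = a.fwd ? L2 : L1;
        if (rv.start < fw.start) continue;            // FR orientation
        int span = rv.start + rvL - fw.start;
        if (span > max_fragment) continue;
        int tot = a.mm + b.mm;
        if ((double)tot / (double)(L1 + L2) > max_mm_ratio) continue;
        if (tot < best) { best = tot; nbest = 1; b1 = a; b2 = b; }
        else if (tot == best) {
          if (!(a.chrom == b1.chrom && a.start == b1.start &&
                b.start == b2.start && a.fwd == b1.fwd)) ++nbest;
        }
      }
    }
    if (best == INT_MAX) { call[i] = 0; continue; }
    if (nbest > 1) { call[i] = 2; continue; }
    call[i] = 1;
    chrom[i] = b1.chrom + 1;
    int st = std::min(b1.start, b2.start);
    int en = std::max(b1.start + L1, b2.start + L2);
    start[i] = st + 1;  end[i] = en;                  // 1-based inclusive
    mm1v[i] = b1.mm; mm2v[i] = b2.mm;
    s1[i] = b1.start + 1; e1[i] = b1.start + L1;
    s2[i] = b2.start + 1; e2[i] = b2.start + L2;
  }
  return DataFrame::create(
      Named("status") = call, Named("chrom_idx") = chrom,
      Named("start") = start, Named("end") = end,
      Named("mm1") = mm1v, Named("mm2") = mm2v,
      Named("start1") = s1, Named("end1") = e1,
      Named("start2") = s2, Named("end2") = e2,
      Named("short_mate") = short_mate);
}
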