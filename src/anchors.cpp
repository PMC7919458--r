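// Exact-match anchor finding on 2-bit encoded k-mers.
//
// Anchors are maximal exact matches seeded by k-mers whose canonical form
// occurs exactly once in each genome (both strands considered). Hash-table
// indexing over megabase sequences is the hot loop of the synteny module,
// hence C++.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

struct KmerRec {
  uint32_t count;
  int32_t chrom;   // 0-based
  int64_t pos;     // 0-based start of forward-scan occurrence
  bool fwd;        // canonical orientation equals forward orientation
};

typedef std::unordered_map<uint64_t, KmerRec> KmerMap;

// Scan all chromosome strings, recording canonical k-mer occurrences.
static void index_genome(const std::vector<std::string>& chroms, int k,
                         KmerMap& map) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (size_t ci = 0; ci < chroms.size(); ++ci) {
    const std::string& s = chroms[ci];
    int64_t n = (int64_t)s.size();
    uint64_t code = 0, rc = 0;
    int valid = 0;
    for (int64_t i = 0; i < n; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; code = 0; rc = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++valid < k) continue;
      if (code == rc) continue;            // palindromic k-mer: ambiguous strand
      uint64_t canon = code < rc ? code : rc;
      auto it = map.find(canon);
      if (it == map.end()) {
        map.emplace(canon, KmerRec{1u, (int32_t)ci, i - k + 1, code < rc});
      } else {
        it->second.count++;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_anchors(CharacterVector ref_chroms, CharacterVector qry_chroms,
                           int k) {
  std::vector<std::string> ref, qry;
  for (R_xlen_t i = 0; i < ref_chroms.size(); ++i) ref.push_back(as<std::string>(ref_chroms[i]));
  for (R_xlen_t i = 0; i < qry_chroms.size(); ++i) qry.push_back(as<std::string>(qry_chroms[i]));

  KmerMap rmap, qmap;
  index_genome(ref, k, rmap);
  index_genome(qry, k, qmap);

  // seed matches: canonical unique in both genomes
  struct Seed { int32_t rc_, qc_; int64_t rpos, qpos; int8_t strand; };
  std::vector<Seed> seeds;
  for (auto& kv : rmap) {
    if (kv.second.count != 1u) continue;
    auto qi = qmap.find(kv.first);
    if (qi == qmap.end() || qi->second.count != 1u) continue;
    int8_t strand = (kv.second.fwd == qi->second.fwd) ? 1 : -1;
    seeds.push_back(Seed{kv.second.chrom, qi->second.chrom,
                         kv.second.pos, qi->second.pos, strand});
  }
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    if (a.rc_ != b.rc_) return a.rc_ < b.rc_;
    return a.rpos < b.rpos;
  });

  // merge same-diagonal runs into maximal segments, then extend exactly
  std::vector<int> out_rc, out_qc;
  std::vector<double> out_rs, out_re, out_qs, out_qe;
  std::vector<int> out_strand;

  size_t i = 0, nseed = seeds.size();
  while (i < nseed) {
    Seed s = seeds[i];
    int64_t r1 = s.rpos, q1 = s.qpos;   // first seed
    int64_t rlast = s.rpos, qlast = s.qpos;
    size_t j = i + 1;
    while (j < nseed) {
      const Seed& t = seeds[j];
      if (t.rc_ != s.rc_ || t.qc_ != s.qc_ || t.strand != s.strand) break;
      if (t.rpos > rlast + k) break;    // not adjacent/overlapping on ref
      if (s.strand == 1) {
        if (t.qpos - t.rpos != q1 - r1) break;           // diagonal changed
      } else {
        if (t.qpos + t.rpos != q1 + r1) break;           // anti-diagonal changed
      }
      rlast = t.rpos; qlast = t.qpos; ++j;
    }
    // merged extents
    int64_t rs = r1, re = rlast + k;                      // ref [rs, re)
    int64_t qs, qe;
    if (s.strand == 1) { qs = q1; qe = qlast + k; }
    else               { qs = qlast; qe = q1 + k; }

    const std::string& R = ref[s.rc_];
    const std::string& Q = qry[s.qc_];
    int64_t Rn = (int64_t)R.size(), Qn = (int64_t)Q.size();
    if (s.strand == 1) {
      while (rs > 0 && qs > 0 && base2bit(R[rs - 1]) >= 0 && R[rs - 1] == Q[qs - 1]) { --rs; --qs; }
      while (re < Rn && qe < Qn && base2bit(R[re]) >= 0 && R[re] == Q[qe]) { ++re; ++qe; }
    } else {
      while (rs > 0 && qe < Qn && base2bit(R[rs - 1]) >= 0 && R[rs - 1] == comp_base(Q[qe])) { --rs; ++qe; }
      while (re < Rn && qs > 0 && base2bit(R[re]) >= 0 && R[re] == comp_base(Q[qs - 1])) { ++re; --qs; }
    }
    out_rc.push_back(s.rc_ + 1); out_qc.push_back(s.qc_ + 1);
    out_rs.push_back((double)rs); out_re.push_back((double)re);
    out_qs.push_back((double)qs); out_qe.push_back((double)qe);
    out_strand.push_back((int)s.strand);
    i = j;
  }

  return DataFrame::create(
    _["ref_chrom_i"] = out_rc, _["ref_start"] = out_rs, _["ref_end"] = out_re,
    _["qry_chrom_i"] = out_qc, _["qry_start"] = out_qs, _["qry_end"] = out_qe,
    _["strand"] = out_strand);
}

// Count mismatching positions between ref[rs, rs+len) and either
// qry[qs, qs+len) (strand +1) or revcomp(qry[qs, qs+len)) (strand -1).
// [[Rcpp::export]]
IntegerVector cpp_count_mismatches(std::string ref, std::string qry,
                                   NumericVector rstart, NumericVector qstart,
                                   NumericVector len, IntegerVector strand) {
  R_xlen_t n = rstart.size();
  IntegerVector out(n);
  for (R_xlen_t g = 0; g < n; ++g) {
    int64_t rs = (int64_t)rstart[g], qs = (int64_t)qstart[g], L = (int64_t)len[g];
    int mm = 0;
    if (strand[g] == 1) {
      for (int64_t i = 0; i < L; ++i) if (ref[rs + i] != qry[qs + i]) ++mm;
    } else {
      for (int64_t i = 0; i < L; ++i) if (ref[rs + i] != comp_base(qry[qs + L - 1 - i])) ++mm;
    }
    out[g] = mm;
  }
  return out;
}

// All occurrences (both strands) of each k-mer of every pattern in the
// subject chromosomes; the subject index is built once for all patterns.
// Occurrence lists per k-mer are capped to keep satellite regions from
// exploding the output.
// [[Rcpp::export]]
DataFrame cpp_kmer_hits(CharacterVector patterns, CharacterVector subj_chroms,
                        int k, int max_hits_per_kmer = 64) {
  std::vector<std::string> subj;
  for (R_xlen_t i = 0; i < subj_chroms.size(); ++i) subj.push_back(as<std::string>(subj_chroms[i]));
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  // index subject: canonical code -> list of (chrom, pos, fwd)
  struct Occ { int32_t chrom; int64_t pos; bool fwd; };
  std::unordered_map<uint64_t, std::vector<Occ> > idx;
  for (size_t ci = 0; ci < subj.size(); ++ci) {
    const std::string& s = subj[ci];
    uint64_t code = 0, rc = 0; int valid = 0;
    for (int64_t i = 0; i < (int64_t)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++valid < k) continue;
      uint64_t canon = code < rc ? code : rc;
      auto& v = idx[canon];
      if ((int)v.size() < max_hits_per_kmer)
        v.push_back(Occ{(int32_t)ci, i - k + 1, code <= rc});
    }
  }

  std::vector<double> out_ppos, out_spos;
  std::vector<int> out_pat, out_chrom, out_strand;
  for (R_xlen_t pi = 0; pi < patterns.size(); ++pi) {
    std::string pattern = as<std::string>(patterns[pi]);
    uint64_t code = 0, rc = 0; int valid = 0;
    for (int64_t i = 0; i < (int64_t)pattern.size(); ++i) {
      int b = base2bit(pattern[i]);
      if (b < 0) { valid = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++valid < k) continue;
      uint64_t canon = code < rc ? code : rc;
      auto it = idx.find(canon);
      if (it == idx.end()) continue;
      bool pat_fwd = code <= rc;
      for (const Occ& o : it->second) {
        out_pat.push_back((int)pi + 1);
        out_ppos.push_back((double)(i - k + 1));
        out_chrom.push_back(o.chrom + 1);
        out_spos.push_back((double)o.pos);
        out_strand.push_back(o.fwd == pat_fwd ? 1 : -1);
      }
    }
  }
  return DataFrame::create(_["pat_i"] = out_pat, _["pat_pos"] = out_ppos,
                           _["subj_chrom_i"] = out_chrom,
                           _["subj_pos"] = out_spos, _["strand"] = out_strand);
}

// Weighted longest increasing subsequence over query positions (strictly
// increasing; pass negated positions for reverse-oriented blocks).
// Returns a logical keep mask maximizing total weight. Fenwick tree for
// prefix maxima over the rank of qry.
// [[Rcpp::export]]
LogicalVector cpp_wlis(NumericVector qry, NumericVector weight) {
  int n = qry.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  // ranks
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return qry[a] < qry[b]; });
  std::vector<int> rank_(n);
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && qry[idx[i]] > qry[idx[i - 1]]) r = i;
    rank_[idx[i]] = r;
  }
  // Fenwick over ranks storing (best dp, index)
  std::vector<double> best(n + 1, 0.0);
  std::vector<int> besti(n + 1, -1);
  std::vector<double> dp(n, 0.0);
  std::vector<int> par(n, -1);
  auto query = [&](int pos, double& b, int& bi) {
    b = 0.0; bi = -1;
    for (int x = pos; x > 0; x -= x & (-x))
      if (best[x] > b) { b = best[x]; bi = besti[x]; }
  };
  auto update = [&](int pos, double val, int i) {
    for (int x = pos; x <= n; x += x & (-x))
      if (val > best[x]) { best[x] = val; besti[x] = i; }
  };
  double gbest = 0.0; int gbesti = -1;
  for (int i = 0; i < n; ++i) {
    double b; int bi;
    query(rank_[i], b, bi);          // strictly smaller rank: ranks are 0-based; pos rank_[i] covers ranks < rank_[i]
    dp[i] = b + weight[i];
    par[i] = bi;
    update(rank_[i] + 1, dp[i], i);
    if (dp[i] > gbest) { gbest = dp[i]; gbesti = i; }
  }
  for (int i = gbesti; i >= 0; i = par[i]) keep[i] = true;
  return keep;
}
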