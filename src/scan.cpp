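// Core k-mer machinery: base-4 encoding, per-chromosome hash indexes,
// seed-chain scanning by position-list intersection, block extension.
// Coordinates are 0-based half-open throughout.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <fstream>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

struct KIndex {
  int k;
  int delta;  // 1 = unfiltered; d = only positions p with p % d == 0 kept
  std::string chrom;
  std::unordered_map<uint64_t, std::vector<int32_t> > table;
};

typedef XPtr<KIndex> KIndexPtr;

static inline int base_digit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;  // N or anything else: no code
}

// Rolling base-4 codes for every window; -1 where the window holds a non-ACGT base.
static std::vector<int64_t> window_codes(const std::string& s, int k) {
  std::vector<int64_t> codes;
  int64_t L = (int64_t)s.size();
  if (L < k) return codes;
  codes.assign((size_t)(L - k + 1), -1);
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int valid = 0;  // consecutive valid bases ending at i
  for (int64_t i = 0; i < L; ++i) {
    int d = base_digit(s[(size_t)i]);
    if (d < 0) {
      valid = 0;
      code = 0;
    } else {
      code = ((code << 2) | (uint64_t)d) & mask;
      ++valid;
    }
    if (i >= k - 1 && valid >= k) codes[(size_t)(i - k + 1)] = (int64_t)code;
  }
  return codes;
}

// [[Rcpp::export]]
NumericVector cpp_encode_kmers(CharacterVector kmers) {
  int n = kmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    double code = 0;
    bool has_n = false;
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[j];
      int d = base_digit(c);
      if (d < 0) {
        if (c == 'N') { has_n = true; continue; }
        stop("invalid base '%s' in k-mer '%s'", std::string(1, c).c_str(), s.c_str());
      }
      code = code * 4.0 + d;
    }
    out[i] = has_n ? NA_REAL : code;
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string seq, int k, std::string chrom) {
  KIndex* idx = new KIndex();
  idx->k = k;
  idx->delta = 1;
  idx->chrom = chrom;
  std::vector<int64_t> codes = window_codes(seq, k);
  for (size_t i = 0; i < codes.size(); ++i)
    if (codes[i] >= 0) idx->table[(uint64_t)codes[i]].push_back((int32_t)i);
  return KIndexPtr(idx, true);
}

// [[Rcpp::export]]
SEXP cpp_filter_index(SEXP xp, int delta) {
  KIndexPtr p(xp);
  KIndex* out = new KIndex();
  out->k = p->k;
  out->delta = delta;
  out->chrom = p->chrom;
  for (std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it = p->table.begin();
       it != p->table.end(); ++it) {
    std::vector<int32_t> kept;
    for (size_t i = 0; i < it->second.size(); ++i)
      if (it->second[i] % delta == 0) kept.push_back(it->second[i]);
    if (!kept.empty()) out->table[it->first] = kept;
  }
  return KIndexPtr(out, true);
}

// [[Rcpp::export]]
List cpp_index_summary(SEXP xp) {
  KIndexPtr p(xp);
  double npos = 0;
  for (std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it = p->table.begin();
       it != p->table.end(); ++it)
    npos += it->second.size();
  return List::create(_["k"] = p->k, _["delta"] = p->delta, _["chrom_id"] = p->chrom,
                      _["n_codes"] = (double)p->table.size(), _["n_positions"] = npos);
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp, std::string kmer) {
  KIndexPtr p(xp);
  if ((int)kmer.size() != p->k) stop("k-mer length %d does not match index k = %d", (int)kmer.size(), p->k);
  uint64_t code = 0;
  for (size_t j = 0; j < kmer.size(); ++j) {
    int d = base_digit(kmer[j]);
    if (d < 0) return IntegerVector(0);
    code = (code << 2) | (uint64_t)d;
  }
  std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it = p->table.find(code);
  if (it == p->table.end()) return IntegerVector(0);
  return wrap(it->second);
}

// Dump the whole table sorted by code then position (for round-trip tests).
// [[Rcpp::export]]
DataFrame cpp_index_dump(SEXP xp) {
  KIndexPtr p(xp);
  std::vector<uint64_t> codes;
  codes.reserve(p->table.size());
  for (std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it = p->table.begin();
       it != p->table.end(); ++it)
    codes.push_back(it->first);
  std::sort(codes.begin(), codes.end());
  std::vector<double> code_col;
  std::vector<int32_t> pos_col;
  for (size_t i = 0; i < codes.size(); ++i) {
    const std::vector<int32_t>& v = p->table.find(codes[i])->second;
    for (size_t j = 0; j < v.size(); ++j) {
      code_col.push_back((double)codes[i]);
      pos_col.push_back(v[j]);
    }
  }
  return DataFrame::create(_["code"] = code_col, _["pos"] = pos_col);
}

static const char INDEX_MAGIC[8] = {'N', 'V', 'A', 'S', 'M', 'I', 'D', 'X'};

// [[Rcpp::export]]
void cpp_save_index(SEXP xp, std::string path) {
  KIndexPtr p(xp);
  std::ofstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  f.write(INDEX_MAGIC, 8);
  int32_t version = 1;
  int32_t k = p->k, delta = p->delta, idlen = (int32_t)p->chrom.size();
  f.write((char*)&version, 4);
  f.write((char*)&k, 4);
  f.write((char*)&delta, 4);
  f.write((char*)&idlen, 4);
  f.write(p->chrom.data(), idlen);
  std::vector<uint64_t> codes;
  for (std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it = p->table.begin();
       it != p->table.end(); ++it)
    codes.push_back(it->first);
  std::sort(codes.begin(), codes.end());
  uint64_t ncodes = codes.size();
  f.write((char*)&ncodes, 8);
  for (size_t i = 0; i < codes.size(); ++i) {
    const std::vector<int32_t>& v = p->table.find(codes[i])->second;
    uint64_t code = codes[i];
    int32_t n = (int32_t)v.size();
    f.write((char*)&code, 8);
    f.write((char*)&n, 4);
    f.write((char*)&v[0], 4 * (size_t)n);
  }
  if (!f) stop("write failure on '%s'", path.c_str());
}

// [[Rcpp::export]]
SEXP cpp_load_index(std::string path, int delta) {
  std::ifstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open index file '%s'", path.c_str());
  char magic[8];
  f.read(magic, 8);
  if (!f || memcmp(magic, INDEX_MAGIC, 8) != 0)
    stop("'%s' is not an index file (bad magic bytes)", path.c_str());
  int32_t version, k, saved_delta, idlen;
  f.read((char*)&version, 4);
  if (version != 1) stop("unsupported index version %d in '%s'", version, path.c_str());
  f.read((char*)&k, 4);
  f.read((char*)&saved_delta, 4);
  f.read((char*)&idlen, 4);
  if (!f || idlen < 0 || idlen > 1000000) stop("corrupt header in '%s'", path.c_str());
  std::string chrom(idlen, '\0');
  f.read(&chrom[0], idlen);
  if (delta > 1 && saved_delta != 1 && delta % saved_delta != 0)
    stop("index '%s' already filtered with delta %d; cannot refilter with %d",
         path.c_str(), saved_delta, delta);
  KIndex* idx = new KIndex();
  idx->k = k;
  idx->delta = std::max(delta, saved_delta);
  idx->chrom = chrom;
  uint64_t ncodes;
  f.read((char*)&ncodes, 8);
  for (uint64_t i = 0; i < ncodes; ++i) {
    uint64_t code;
    int32_t n;
    f.read((char*)&code, 8);
    f.read((char*)&n, 4);
    if (!f || n < 0) { delete idx; stop("corrupt record in '%s'", path.c_str()); }
    std::vector<int32_t> v((size_t)n);
    f.read((char*)&v[0], 4 * (size_t)n);
    if (!f) { delete idx; stop("truncated index file '%s'", path.c_str()); }
    if (delta > 1) {
      std::vector<int32_t> kept;
      for (size_t j = 0; j < v.size(); ++j)
        if (v[j] % delta == 0) kept.push_back(v[j]);
      if (!kept.empty()) idx->table[code] = kept;
    } else {
      idx->table[code] = v;
    }
  }
  return KIndexPtr(idx, true);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      char rc;
      switch (c) {
        case 'A': rc = 'T'; break;
        case 'C': rc = 'G'; break;
        case 'G': rc = 'C'; break;
        case 'T': rc = 'A'; break;
        case 'N': rc = 'N'; break;
        default: stop("invalid base '%s' in sequence", std::string(1, c).c_str());
      }
      r[j] = rc;
    }
    out[i] = r;
  }
  return out;
}

// Seed-chain scan. `period` is the distance between consecutive seed starts
// within a chain (k + g; k itself at full density). A chain starts at the
// current cursor when its seed has at least one indexed position, and grows by
// intersecting the surviving reference-start set with the next seed's
// positions shifted by the chain offset. The chain is emitted when the
// surviving set is unique and the whole-seed span reaches min_span. The
// cursor restarts at the base following the last matched seed, so each query
// base is examined at most once per orientation.
// [[Rcpp::export]]
List cpp_scan(SEXP xp, std::string query, int period, int min_span) {
  KIndexPtr p(xp);
  int k = p->k;
  std::vector<int64_t> qc = window_codes(query, k);
  int64_t nq = (int64_t)qc.size();
  std::vector<int32_t> qs, qe, rs, nseeds;
  double lookups = 0;
  int64_t q = 0;
  while (q < nq) {
    int64_t c0 = qc[(size_t)q];
    if (c0 < 0) { ++q; continue; }
    ++lookups;
    std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it =
        p->table.find((uint64_t)c0);
    if (it == p->table.end()) { ++q; continue; }
    std::vector<int32_t> S = it->second;
    int64_t q0 = q, qlast = q;
    int ns = 1;
    while (true) {
      int64_t qn = qlast + period;
      if (qn >= nq) break;
      int64_t cn = qc[(size_t)qn];
      if (cn < 0) break;
      ++lookups;
      std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator it2 =
          p->table.find((uint64_t)cn);
      if (it2 == p->table.end()) break;
      const std::vector<int32_t>& Pn = it2->second;
      int64_t off = qn - q0;
      std::vector<int32_t> S2;
      for (size_t i = 0; i < S.size(); ++i) {
        int64_t target = (int64_t)S[i] + off;
        if (target <= INT32_MAX &&
            std::binary_search(Pn.begin(), Pn.end(), (int32_t)target))
          S2.push_back(S[i]);
      }
      if (S2.empty()) break;
      S.swap(S2);
      qlast = qn;
      ++ns;
    }
    int32_t span = (int32_t)(qlast + k - q0);
    if (S.size() == 1 && span >= min_span) {
      qs.push_back((int32_t)q0);
      qe.push_back((int32_t)(q0 + span));
      rs.push_back(S[0]);
      nseeds.push_back(ns);
    }
    q = qlast + k;  // restart at the base following the region
  }
  DataFrame regions = DataFrame::create(
      _["q_start"] = qs, _["q_end"] = qe, _["r_start"] = rs, _["n_seeds"] = nseeds);
  return List::create(_["regions"] = regions, _["lookups"] = lookups);
}

// Number of k-mer windows of seq that occur in the index (novelty check).
// [[Rcpp::export]]
double cpp_count_hits(SEXP xp, std::string seq) {
  KIndexPtr p(xp);
  std::vector<int64_t> codes = window_codes(seq, p->k);
  double hits = 0;
  for (size_t i = 0; i < codes.size(); ++i)
    if (codes[i] >= 0 && p->table.count((uint64_t)codes[i])) ++hits;
  return hits;
}

// Grow each block base-by-base in both directions while query and reference
// agree on an unambiguous base (N never matches). Blocks are gap-free, so the
// query and reference intervals move together.
// [[Rcpp::export]]
DataFrame cpp_extend_blocks(std::string query, std::string ref,
                            IntegerVector q_start, IntegerVector q_end,
                            IntegerVector r_start) {
  int n = q_start.size();
  int64_t Lq = (int64_t)query.size(), Lr = (int64_t)ref.size();
  IntegerVector oqs(n), oqe(n), ors(n), ore(n);
  for (int i = 0; i < n; ++i) {
    int64_t qs = q_start[i], qe = q_end[i], rs = r_start[i];
    int64_t re = rs + (qe - qs);
    while (qs > 0 && rs > 0) {
      char a = query[(size_t)(qs - 1)], b = ref[(size_t)(rs - 1)];
      if (a != b || base_digit(a) < 0) break;
      --qs; --rs;
    }
    while (qe < Lq && re < Lr) {
      char a = query[(size_t)qe], b = ref[(size_t)re];
      if (a != b || base_digit(a) < 0) break;
      ++qe; ++re;
    }
    oqs[i] = (int32_t)qs; oqe[i] = (int32_t)qe;
    ors[i] = (int32_t)rs; ore[i] = (int32_t)re;
  }
  return DataFrame::create(_["q_start"] = oqs, _["q_end"] = oqe,
                           _["r_start"] = ors, _["r_end"] = ore);
}
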