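// Core sequence kernels: canonical k-mer counting, case-specific k-mer
// extraction, split-key Hamming-1 counterpart search, read retrieval by
// 1-mismatch k-mer screen, greedy overlap-consensus read assembly, and
// exact hypergeometric tail enumeration (test oracle).
//
// k-mers are 2-bit encoded (A=0, C=1, G=2, T=3) in a uint64, so k <= 31.
// Windows containing any non-ACGT base (N from quality masking) are skipped.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>
#include <array>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  case 'N': case 'n': return 'N';
  default: return 'N';
  }
}

static inline std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// encode s[from, from+k); returns false if a non-ACGT base is hit
static bool encode_kmer(const char *s, int k, uint64_t &out) {
  uint64_t e = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    e = (e << 2) | (uint64_t)b;
  }
  out = e;
  return true;
}

static inline uint64_t revcomp_enc(uint64_t e, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (e & 3ULL));
    e >>= 2;
  }
  return r;
}

static std::string decode_kmer(uint64_t e, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[e & 3ULL];
    e >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    for (char c : s) {
      if (base2bits(c) < 0)
        stop("k-mer contains a non-ACGT character: '%s'", s.c_str());
    }
    std::string r = revcomp_str(s);
    out[i] = (r < s) ? r : s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// quality-aware read cleaning (Phred+33)

// BWA-style 3' quality trim: cut at the suffix position maximising the
// running sum of (cutoff - q) accumulated from the 3' end; on ties keep
// more bases. Optionally apply the mirrored rule to the 5' end first.
// [[Rcpp::export]]
List cpp_trim_quality(CharacterVector seqs, CharacterVector quals,
                      int cutoff, bool five_prime = false) {
  R_xlen_t n = seqs.size();
  CharacterVector oseq(n), oqual(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size()) stop("read %d: bases/quals length mismatch", (int)(i + 1));
    int lo = 0, hi = (int)s.size();
    if (five_prime) {
      long best = 0, run = 0;
      int cut = 0;
      for (int j = 0; j < hi; ++j) {
        run += cutoff - ((int)q[j] - 33);
        if (run > best) { best = run; cut = j + 1; }
      }
      lo = cut;
    }
    {
      long best = 0, run = 0;
      int cut = hi;
      for (int j = hi - 1; j >= lo; --j) {
        run += cutoff - ((int)q[j] - 33);
        if (run > best) { best = run; cut = j; }
      }
      hi = cut;
    }
    if (lo >= hi) { oseq[i] = ""; oqual[i] = ""; }
    else { oseq[i] = s.substr(lo, hi - lo); oqual[i] = q.substr(lo, hi - lo); }
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual);
}

// replace every base with Phred score strictly below threshold by N
// [[Rcpp::export]]
CharacterVector cpp_mask_low_quality(CharacterVector seqs, CharacterVector quals,
                                     int threshold) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size()) stop("read %d: bases/quals length mismatch", (int)(i + 1));
    for (size_t j = 0; j < s.size(); ++j)
      if (((int)q[j] - 33) < threshold) s[j] = 'N';
    out[i] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// canonical k-mer counting

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 5 || k > 31 || k % 2 == 0) stop("k must be odd and in [5, 31]");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 20);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  R_xlen_t n = seqs.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP el = seqs[i];
    const char *s = CHAR(el);
    int len = (int)LENGTH(el);
    uint64_t fwd = 0, rev = 0;
    int valid = 0; // number of consecutive valid bases ending here
    for (int j = 0; j < len; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | (((uint64_t)(3 - b)) << shift);
      if (++valid >= k) {
        uint64_t canon = (fwd < rev) ? fwd : rev;
        ++tab[canon];
      }
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto &kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  R_xlen_t m = (R_xlen_t)keys.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmer[i] = decode_kmer(keys[i], k);
    count[i] = (int)tab[keys[i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// ---------------------------------------------------------------------------
// case-specific k-mer extraction

// [[Rcpp::export]]
List cpp_extract_cs(CharacterVector case_kmer, IntegerVector case_count,
                    CharacterVector ctrl_filt_kmer,
                    CharacterVector ctrl_raw_kmer, IntegerVector ctrl_raw_count,
                    int k, int max_control_count) {
  std::unordered_set<uint64_t> filt;
  filt.reserve(ctrl_filt_kmer.size() * 2 + 1);
  for (R_xlen_t i = 0; i < ctrl_filt_kmer.size(); ++i) {
    uint64_t e;
    if (!encode_kmer(CHAR((SEXP)ctrl_filt_kmer[i]), k, e)) stop("bad control k-mer");
    filt.insert(e);
  }
  std::unordered_map<uint64_t, int> raw;
  raw.reserve(ctrl_raw_kmer.size() * 2 + 1);
  for (R_xlen_t i = 0; i < ctrl_raw_kmer.size(); ++i) {
    uint64_t e;
    if (!encode_kmer(CHAR((SEXP)ctrl_raw_kmer[i]), k, e)) stop("bad control k-mer");
    raw[e] = ctrl_raw_count[i];
  }
  std::vector<R_xlen_t> keep;
  std::vector<int> rawc;
  for (R_xlen_t i = 0; i < case_kmer.size(); ++i) {
    uint64_t e;
    if (!encode_kmer(CHAR((SEXP)case_kmer[i]), k, e)) stop("bad case k-mer");
    if (filt.count(e)) continue;
    auto it = raw.find(e);
    int rc = (it == raw.end()) ? 0 : it->second;
    if (rc > max_control_count) continue;
    keep.push_back(i);
    rawc.push_back(rc);
  }
  R_xlen_t m = (R_xlen_t)keep.size();
  CharacterVector okmer(m);
  IntegerVector ocount(m), oraw(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    okmer[i] = case_kmer[keep[i]];
    ocount[i] = case_count[keep[i]];
    oraw[i] = rawc[i];
  }
  return List::create(_["kmer"] = okmer, _["case_count"] = ocount,
                      _["control_raw"] = oraw);
}

// count lookup with internal canonicalisation; absent -> 0
// [[Rcpp::export]]
IntegerVector cpp_lookup_counts(CharacterVector table_kmer, IntegerVector table_count,
                                CharacterVector query, int k) {
  std::unordered_map<uint64_t, int> tab;
  tab.reserve(table_kmer.size() * 2 + 1);
  for (R_xlen_t i = 0; i < table_kmer.size(); ++i) {
    uint64_t e;
    if (!encode_kmer(CHAR((SEXP)table_kmer[i]), k, e)) stop("bad table k-mer");
    tab[e] = table_count[i];
  }
  IntegerVector out(query.size());
  for (R_xlen_t i = 0; i < query.size(); ++i) {
    uint64_t e;
    if (!encode_kmer(CHAR((SEXP)query[i]), k, e)) { out[i] = 0; continue; }
    uint64_t r = revcomp_enc(e, k);
    uint64_t c = (e < r) ? e : r;
    auto it = tab.find(c);
    out[i] = (it == tab.end()) ? 0 : it->second;
  }
  return out;
}

// membership of canonical queries across a panel table
// [[Rcpp::export]]
LogicalVector cpp_in_table(CharacterVector table_kmer, CharacterVector query, int k) {
  std::unordered_set<uint64_t> tab;
  tab.reserve(table_kmer.size() * 2 + 1);
  for (R_xlen_t i = 0; i < table_kmer.size(); ++i) {
    uint64_t e;
    if (!encode_kmer(CHAR((SEXP)table_kmer[i]), k, e)) stop("bad table k-mer");
    tab.insert(e);
  }
  LogicalVector out(query.size());
  for (R_xlen_t i = 0; i < query.size(); ++i) {
    uint64_t e;
    encode_kmer(CHAR((SEXP)query[i]), k, e);
    out[i] = tab.count(e) > 0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// split-key Hamming-1 counterpart matching
//
// Keys are the (k-1)/2-base prefix and suffix of each cs-kmer, in both
// orientations. Control k-mers (both orientations) sharing a key land in the
// same bucket; bucket members at Hamming distance exactly 1 form candidate
// pairs. A single mismatch cannot destroy both end keys, so the search is
// complete. Per cs-kmer the counterpart with the highest control count is
// kept (ties: lexicographically smallest in the cs-kmer's orientation).

// distance-1 test on 2-bit encodings; returns mismatch offset or -1
static inline int hamming1_pos(uint64_t a, uint64_t b, int k) {
  uint64_t x = a ^ b;
  if (x == 0) return -1;
  int hi = 63 - __builtin_clzll(x);
  int slot = hi / 2;                 // slot 0 = last base
  uint64_t slotmask = 3ULL << (2 * slot);
  if (x & ~slotmask) return -1;      // differences outside one slot
  return k - 1 - slot;
}

// [[Rcpp::export]]
DataFrame cpp_match_counterparts(CharacterVector cs, CharacterVector ctrl_kmer,
                                 IntegerVector ctrl_count, int k) {
  if (k % 2 == 0) stop("k must be odd");
  const int klen = (k - 1) / 2;
  const uint64_t keymask = (1ULL << (2 * klen)) - 1;
  const int sufshift = 0, preshift = 2 * (k - klen);

  auto prekey = [&](uint64_t e) { return (e >> preshift) & keymask; };
  auto sufkey = [&](uint64_t e) { return (e >> sufshift) & keymask; };

  R_xlen_t ncs = cs.size();
  std::vector<uint64_t> csf(ncs), csr(ncs);
  std::unordered_set<uint64_t> keyset;
  keyset.reserve(ncs * 4 + 1);
  for (R_xlen_t i = 0; i < ncs; ++i) {
    uint64_t e;
    if (!encode_kmer(CHAR((SEXP)cs[i]), k, e)) stop("bad cs-kmer");
    csf[i] = e;
    csr[i] = revcomp_enc(e, k);
    keyset.insert(prekey(e)); keyset.insert(sufkey(e));
    keyset.insert(prekey(csr[i])); keyset.insert(sufkey(csr[i]));
  }

  // bucket: key -> member list; member: (oriented encoding, index, is_cs, is_rc)
  struct Member { uint64_t e; int idx; bool cs; bool rc; };
  std::unordered_map<uint64_t, std::vector<Member>> buckets;
  buckets.reserve(keyset.size() * 2 + 1);
  auto add = [&](uint64_t key, uint64_t e, int idx, bool is_cs, bool is_rc) {
    if (!keyset.count(key)) return;
    auto &v = buckets[key];
    for (auto &m : v)
      if (m.e == e && m.idx == idx && m.cs == is_cs && m.rc == is_rc) return;
    v.push_back({e, idx, is_cs, is_rc});
  };
  for (R_xlen_t i = 0; i < ncs; ++i) {
    add(prekey(csf[i]), csf[i], (int)i, true, false);
    add(sufkey(csf[i]), csf[i], (int)i, true, false);
    add(prekey(csr[i]), csr[i], (int)i, true, true);
    add(sufkey(csr[i]), csr[i], (int)i, true, true);
  }
  for (R_xlen_t i = 0; i < ctrl_kmer.size(); ++i) {
    uint64_t e;
    if (!encode_kmer(CHAR((SEXP)ctrl_kmer[i]), k, e)) stop("bad control k-mer");
    uint64_t r = revcomp_enc(e, k);
    add(prekey(e), e, (int)i, false, false);
    add(sufkey(e), e, (int)i, false, false);
    add(prekey(r), r, (int)i, false, true);
    add(sufkey(r), r, (int)i, false, true);
  }

  // best counterpart per cs-kmer, in the cs-kmer's stored orientation
  struct Best { bool has = false; uint64_t ct; int pos; int count; };
  std::vector<Best> best(ncs);
  for (auto &kv : buckets) {
    auto &v = kv.second;
    for (size_t a = 0; a < v.size(); ++a) {
      if (!v[a].cs) continue;
      for (size_t b = 0; b < v.size(); ++b) {
        if (v[b].cs) continue;
        int pos = hamming1_pos(v[a].e, v[b].e, k);
        if (pos < 0) continue;
        uint64_t ct = v[b].e;
        if (v[a].rc) { ct = revcomp_enc(ct, k); pos = k - 1 - pos; }
        int cnt = ctrl_count[v[b].idx];
        Best &bb = best[v[a].idx];
        if (!bb.has || cnt > bb.count || (cnt == bb.count && ct < bb.ct)) {
          bb.has = true; bb.ct = ct; bb.pos = pos; bb.count = cnt;
        }
      }
    }
  }

  std::vector<int> idx;
  for (R_xlen_t i = 0; i < ncs; ++i) if (best[i].has) idx.push_back((int)i);
  R_xlen_t m = (R_xlen_t)idx.size();
  CharacterVector ocs(m), oct(m), ca(m), na(m);
  IntegerVector pos(m), cnt(m);
  for (R_xlen_t j = 0; j < m; ++j) {
    int i = idx[j];
    ocs[j] = cs[i];
    std::string ctstr = decode_kmer(best[i].ct, k);
    oct[j] = ctstr;
    pos[j] = best[i].pos;
    std::string csstr = as<std::string>(cs[i]);
    ca[j] = std::string(1, csstr[best[i].pos]);
    na[j] = std::string(1, ctstr[best[i].pos]);
    cnt[j] = best[i].count;
  }
  return DataFrame::create(_["cs_kmer"] = ocs, _["ct_kmer"] = oct,
                           _["pos"] = pos, _["case_allele"] = ca,
                           _["control_allele"] = na, _["ct_count"] = cnt,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// read retrieval: reads containing a window within Hamming distance 1 of any
// member k-mer of any listed contig (either orientation)

// [[Rcpp::export]]
List cpp_retrieve_reads_multi(List contig_members, CharacterVector reads, int k) {
  int ncontig = contig_members.size();
  std::unordered_map<uint64_t, std::vector<int>> nbr; // canonical enc -> contig ids
  nbr.reserve(1 << 16);
  for (int c = 0; c < ncontig; ++c) {
    CharacterVector mem = contig_members[c];
    for (R_xlen_t i = 0; i < mem.size(); ++i) {
      uint64_t e;
      if (!encode_kmer(CHAR((SEXP)mem[i]), k, e)) stop("bad member k-mer");
      // all Hamming<=1 variants
      for (int p = -1; p < k; ++p) {
        for (int b = 0; b < 4; ++b) {
          uint64_t v = e;
          if (p >= 0) {
            int slot = k - 1 - p;
            v = (e & ~(3ULL << (2 * slot))) | ((uint64_t)b << (2 * slot));
          } else if (b > 0) continue;
          uint64_t r = revcomp_enc(v, k);
          uint64_t canon = (v < r) ? v : r;
          auto &vec = nbr[canon];
          if (vec.empty() || vec.back() != c) vec.push_back(c);
        }
      }
    }
  }
  std::vector<std::vector<int>> hits(ncontig);
  std::vector<int> lastread(ncontig, -1);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP el = reads[i];
    const char *s = CHAR(el);
    int len = (int)LENGTH(el);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int j = 0; j < len; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { valid = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | (((uint64_t)(3 - b)) << shift);
      if (++valid < k) continue;
      uint64_t canon = (fwd < rev) ? fwd : rev;
      auto it = nbr.find(canon);
      if (it == nbr.end()) continue;
      for (int c : it->second) {
        if (lastread[c] != (int)i) { lastread[c] = (int)i; hits[c].push_back((int)i + 1); }
      }
    }
  }
  List out(ncontig);
  for (int c = 0; c < ncontig; ++c) out[c] = wrap(hits[c]);
  return out;
}

// ---------------------------------------------------------------------------
// greedy overlap-consensus assembly of retrieved control reads
//
// Repeatedly merges the pair of current consensus sequences with the longest
// exact suffix-prefix overlap (>= min_overlap), considering both
// orientations of the incoming sequence; N acts as a wildcard and consensus
// columns are re-called by majority vote over supporting reads.

struct AsmItem {
  std::string cons;
  std::string rc;    // cached reverse complement of cons
  std::vector<std::array<int, 4>> votes;
  int nreads;
  bool alive;
};

static void recall_consensus(AsmItem &it, size_t from, size_t to) {
  for (size_t i = from; i < to && i < it.cons.size(); ++i) {
    int best = -1, bestc = 0;
    for (int b = 0; b < 4; ++b)
      if (it.votes[i][b] > bestc) { bestc = it.votes[i][b]; best = b; }
    it.cons[i] = (best < 0) ? 'N' : BITS2BASE[best];
  }
}

// longest exact overlap (suffix of a, prefix of b), N wildcard; seeded
// scan: slide b's leading bases along a's suffix and verify on seed hits
static int max_overlap(const std::string &a, const std::string &b, int min_ovl) {
  int la = (int)a.size(), lb = (int)b.size();
  if (la < min_ovl || lb < min_ovl) return 0;
  int s = std::min(12, min_ovl);
  int pmin = std::max(0, la - lb);
  int pmax = la - min_ovl;
  for (int p = pmin; p <= pmax; ++p) {
    bool ok = true;
    for (int t = 0; t < s; ++t) {
      char ca = a[p + t], cb = b[t];
      if (ca != cb && ca != 'N' && cb != 'N') { ok = false; break; }
    }
    if (!ok) continue;
    int L = la - p;
    for (int t = s; t < L; ++t) {
      char ca = a[p + t], cb = b[t];
      if (ca != cb && ca != 'N' && cb != 'N') { ok = false; break; }
    }
    if (ok) return L;
  }
  return 0;
}

static AsmItem flip_item(const AsmItem &x) {
  AsmItem r;
  r.cons = x.rc;
  r.rc = x.cons;
  r.nreads = x.nreads;
  r.alive = x.alive;
  r.votes.resize(x.votes.size());
  for (size_t i = 0; i < x.votes.size(); ++i) {
    const auto &v = x.votes[x.votes.size() - 1 - i];
    r.votes[i] = {v[3], v[2], v[1], v[0]};
  }
  return r;
}

// [[Rcpp::export]]
List cpp_assemble_reads(CharacterVector reads, int min_overlap) {
  int n = reads.size();
  std::vector<AsmItem> items;
  items.reserve(n);
  for (int i = 0; i < n; ++i) {
    AsmItem it;
    it.cons = as<std::string>(reads[i]);
    it.rc = revcomp_str(it.cons);
    it.nreads = 1;
    it.alive = true;
    it.votes.assign(it.cons.size(), {0, 0, 0, 0});
    for (size_t j = 0; j < it.cons.size(); ++j) {
      int b = base2bits(it.cons[j]);
      if (b >= 0) it.votes[j][b] = 1;
    }
    items.push_back(std::move(it));
  }
  if (n > 1) {
    // overlap cache over the three junction types per ordered pair (i, j):
    // o=0: i -> j, o=1: i -> rc(j), o=2: rc(i) -> j (the fourth type,
    // rc(i) -> rc(j), is the reverse complement of j -> i and so covered
    // by the ordered pair (j, i))
    std::vector<std::vector<int>> ov(n, std::vector<int>(3 * n, 0));
    auto compute = [&](int i, int j) {
      if (i == j || !items[i].alive || !items[j].alive) {
        ov[i][3 * j] = ov[i][3 * j + 1] = ov[i][3 * j + 2] = 0;
        return;
      }
      ov[i][3 * j] = max_overlap(items[i].cons, items[j].cons, min_overlap);
      ov[i][3 * j + 1] = max_overlap(items[i].cons, items[j].rc, min_overlap);
      ov[i][3 * j + 2] = max_overlap(items[i].rc, items[j].cons, min_overlap);
    };
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) compute(i, j);
    while (true) {
      int bi = -1, bj = -1, bo = 0, bL = 0;
      for (int i = 0; i < n; ++i) {
        if (!items[i].alive) continue;
        for (int j = 0; j < n; ++j) {
          if (i == j || !items[j].alive) continue;
          for (int o = 0; o < 3; ++o) {
            int L = ov[i][3 * j + o];
            if (L > bL) { bL = L; bi = i; bj = j; bo = o; }
          }
        }
      }
      if (bL < min_overlap || bi < 0) break;
      if (bo == 2) items[bi] = flip_item(items[bi]);
      AsmItem other = (bo == 1) ? flip_item(items[bj]) : items[bj];
      AsmItem &a = items[bi];
      size_t off = a.cons.size() - bL;
      size_t newlen = off + other.cons.size();
      a.votes.resize(newlen, {0, 0, 0, 0});
      a.cons.resize(newlen, 'N');
      for (size_t p = 0; p < other.cons.size(); ++p)
        for (int b = 0; b < 4; ++b) a.votes[off + p][b] += other.votes[p][b];
      recall_consensus(a, off, newlen);
      a.rc = revcomp_str(a.cons);
      a.nreads += other.nreads;
      items[bj].alive = false;
      for (int j = 0; j < n; ++j)
        if (j != bi) { compute(bi, j); compute(j, bi); }
    }
  }
  std::vector<int> alive;
  for (int i = 0; i < n; ++i) if (items[i].alive) alive.push_back(i);
  // longest first; ties by sequence for determinism
  std::sort(alive.begin(), alive.end(), [&](int x, int y) {
    if (items[x].cons.size() != items[y].cons.size())
      return items[x].cons.size() > items[y].cons.size();
    return items[x].cons < items[y].cons;
  });
  CharacterVector cons(alive.size());
  IntegerVector nr(alive.size());
  for (size_t i = 0; i < alive.size(); ++i) {
    cons[i] = items[alive[i]].cons;
    nr[i] = items[alive[i]].nreads;
  }
  return List::create(_["consensus"] = cons, _["n_reads"] = nr);
}

// ---------------------------------------------------------------------------
// exact hypergeometric upper-tail enumeration (independent test oracle for
// the Fisher exact test route; summation over the support with a
// precomputed log-factorial table)

// [[Rcpp::export]]
NumericVector cpp_hyper_tail_enum(IntegerVector cs_case, IntegerVector cov_case,
                                  IntegerVector cs_ctrl, IntegerVector cov_ctrl) {
  R_xlen_t n = cs_case.size();
  int maxN = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    maxN = std::max(maxN, cov_case[i] + cov_ctrl[i]);
  std::vector<long double> lf(maxN + 1, 0.0L);
  for (int i = 1; i <= maxN; ++i) lf[i] = lf[i - 1] + logl((long double)i);
  auto lchoose = [&](int a, int b) -> long double {
    if (b < 0 || b > a) return -1e30L;
    return lf[a] - lf[b] - lf[a - b];
  };
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int a = cs_case[i], Nc = cov_case[i], b = cs_ctrl[i], Nn = cov_ctrl[i];
    int N = Nc + Nn, K = a + b;
    if (N == 0 || K == 0) { out[i] = 1.0; continue; }
    long double denom = lchoose(N, Nc);
    long double p = 0.0L;
    int xmax = std::min(K, Nc);
    for (int x = a; x <= xmax; ++x) {
      if (K - x > Nn) continue;
      p += expl(lchoose(K, x) + lchoose(N - K, Nc - x) - denom);
    }
    out[i] = (double)std::min(p, (long double)1.0);
  }
  return out;
}

// ---------------------------------------------------------------------------
// unique-occurrence k-mer location in a genome (placement anchors)

// [[Rcpp::export]]
List cpp_locate_kmers(std::string genome, CharacterVector queries, int k) {
  struct Loc { int pos; uint64_t fwd; int count; };
  std::unordered_map<uint64_t, Loc> idx;
  idx.reserve(genome.size() * 2 + 1);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t j = 0; j < genome.size(); ++j) {
    int b = base2bits(genome[j]);
    if (b < 0) { valid = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - b)) << shift);
    if (++valid < k) continue;
    uint64_t canon = (fwd < rev) ? fwd : rev;
    auto it = idx.find(canon);
    if (it == idx.end()) idx[canon] = {(int)(j - k + 1), fwd, 1};
    else it->second.count++;
  }
  R_xlen_t n = queries.size();
  IntegerVector pos(n), strand(n);
  LogicalVector ambiguous(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t e;
    pos[i] = NA_INTEGER; strand[i] = NA_INTEGER; ambiguous[i] = false;
    if (!encode_kmer(CHAR((SEXP)queries[i]), k, e)) continue;
    uint64_t r = revcomp_enc(e, k);
    uint64_t canon = (e < r) ? e : r;
    auto it = idx.find(canon);
    if (it == idx.end()) continue;
    if (it->second.count > 1) { ambiguous[i] = true; continue; }
    pos[i] = it->second.pos;
    strand[i] = (e == it->second.fwd) ? 1 : -1;
  }
  return List::create(_["pos0"] = pos, _["strand"] = strand,
                      _["ambiguous"] = ambiguous);
}
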