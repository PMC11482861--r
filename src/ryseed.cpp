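// Bit-packed kmer / RYmer encodings, Wang hashing, minimizer window scans,
// seed comparison, alignment extension and damage bookkeeping.
//
// 64-bit keys cross the R boundary as fixed-width 16-character lowercase hex
// strings (R doubles lose exactness past 2^53, too narrow for 62-bit keys).

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

static const int MAX_KMER = 31;   // 62 usable bits at 2 bits/base
static const int MAX_RYMER = 62;  // 62 usable bits at 1 bit/base

// ---- base codes: A=00 C=01 G=10 T=11; purine <=> even code (low bit 0) ----

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline std::string u64hex(uint64_t x) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
  return std::string(buf);
}

static inline uint64_t hex2u64(const char* s) {
  uint64_t v = 0;
  for (int i = 0; i < 16 && s[i]; ++i) {
    char c = s[i];
    int d = (c >= '0' && c <= '9') ? c - '0'
          : (c >= 'a' && c <= 'f') ? c - 'a' + 10
          : (c >= 'A' && c <= 'F') ? c - 'A' + 10 : 0;
    v = (v << 4) | (uint64_t)d;
  }
  return v;
}

// Thomas Wang's 64-bit integer mix (the invertible xor-shift/multiply-free
// ladder). Pinned: this exact variant is part of the index format.
static inline uint64_t wang_hash64(uint64_t key) {
  key = (~key) + (key << 21);
  key = key ^ (key >> 24);
  key = (key + (key << 3)) + (key << 8);
  key = key ^ (key >> 14);
  key = (key + (key << 2)) + (key << 4);
  key = key ^ (key >> 28);
  key = key + (key << 31);
  return key;
}

// ---------------------------------------------------------------------------
// encoding / decoding

// [[Rcpp::export]]
CharacterVector cpp_encode_kmer(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t len = strlen(s);
    if (len < 1 || len > (size_t)MAX_KMER)
      stop("kmer length must be in 1..%d (got %d)", MAX_KMER, (int)len);
    uint64_t bits = 0;
    for (size_t j = 0; j < len; ++j) {
      int c = base2code(s[j]);
      if (c < 0)
        stop("sequence contains a base outside {A,C,G,T}: '%c'", s[j]);
      bits = (bits << 2) | (uint64_t)c;
    }
    out[i] = u64hex(bits);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmer(CharacterVector keys, IntegerVector k) {
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    int kk = k.size() == 1 ? k[0] : k[i];
    uint64_t bits = hex2u64(CHAR(STRING_ELT(keys, i)));
    buf.assign(kk, 'A');
    for (int j = kk - 1; j >= 0; --j) {
      buf[j] = CODE2BASE[bits & 3ULL];
      bits >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_encode_rymer(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t len = strlen(s);
    if (len < 1 || len > (size_t)MAX_RYMER)
      stop("RYmer length must be in 1..%d (got %d)", MAX_RYMER, (int)len);
    uint64_t bits = 0;
    for (size_t j = 0; j < len; ++j) {
      int c = base2code(s[j]);
      if (c < 0) {
        // accept R/Y symbols directly as well
        if (s[j] == 'R' || s[j] == 'r') c = 0;
        else if (s[j] == 'Y' || s[j] == 'y') c = 1;
        else stop("sequence contains a base outside {A,C,G,T,R,Y}: '%c'", s[j]);
        bits = (bits << 1) | (uint64_t)c;
      } else {
        bits = (bits << 1) | (uint64_t)(c & 1);  // purine even, pyrimidine odd
      }
    }
    out[i] = u64hex(bits);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_rymer(CharacterVector keys, IntegerVector k) {
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    int kk = k.size() == 1 ? k[0] : k[i];
    uint64_t bits = hex2u64(CHAR(STRING_ELT(keys, i)));
    buf.assign(kk, 'R');
    for (int j = kk - 1; j >= 0; --j) {
      buf[j] = (bits & 1ULL) ? 'Y' : 'R';
      bits >>= 1;
    }
    out[i] = buf;
  }
  return out;
}

static inline uint64_t project_kmer(uint64_t bits, int k) {
  // per-base 2-bit -> 1-bit: keep the low bit ({A,G} even -> 0, {C,T} -> 1)
  uint64_t ry = 0;
  for (int j = k - 1; j >= 0; --j) {
    ry |= ((bits >> (2 * j)) & 1ULL) << j;
  }
  return ry;
}

// [[Rcpp::export]]
CharacterVector cpp_kmer_to_rymer(CharacterVector keys, IntegerVector k) {
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int kk = k.size() == 1 ? k[0] : k[i];
    out[i] = u64hex(project_kmer(hex2u64(CHAR(STRING_ELT(keys, i))), kk));
  }
  return out;
}

static inline uint64_t revcomp_code(uint64_t bits, int k) {
  uint64_t rc = 0;
  for (int j = 0; j < k; ++j) {
    rc = (rc << 2) | (3ULL - (bits & 3ULL));
    bits >>= 2;
  }
  return rc;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp_kmer(CharacterVector keys, IntegerVector k) {
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int kk = k.size() == 1 ? k[0] : k[i];
    out[i] = u64hex(revcomp_code(hex2u64(CHAR(STRING_ELT(keys, i))), kk));
  }
  return out;
}

// RY reverse complement: reverse bit order, flip every bit
// (complementation swaps purine <-> pyrimidine).
// [[Rcpp::export]]
CharacterVector cpp_revcomp_rymer(CharacterVector keys, IntegerVector k) {
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int kk = k.size() == 1 ? k[0] : k[i];
    uint64_t bits = hex2u64(CHAR(STRING_ELT(keys, i)));
    uint64_t rc = 0;
    for (int j = 0; j < kk; ++j) {
      rc = (rc << 1) | (1ULL - (bits & 1ULL));
      bits >>= 1;
    }
    out[i] = u64hex(rc);
  }
  return out;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp_seq(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t len = strlen(s);
    buf.resize(len);
    for (size_t j = 0; j < len; ++j) buf[j] = comp_base(s[len - 1 - j]);
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_hash64(CharacterVector keys) {
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = u64hex(wang_hash64(hex2u64(CHAR(STRING_ELT(keys, i)))));
  return out;
}

// ---------------------------------------------------------------------------
// minimizer window scan
//
// Windowing scheme shared by index construction and read querying:
//  * every kmer start position free of ambiguous bases is a candidate;
//  * each candidate is canonicalised: of the forward and reverse-complement
//    encodings the one with the smaller Wang hash wins, ties to forward;
//  * every window of w consecutive start positions contributes all candidates
//    attaining the window's minimum canonical hash;
//  * a sequence with >= 1 but < w candidate start positions is treated as a
//    single truncated window (otherwise short fragments could never seed).

struct ScanHit {
  int offset;
  int orient;  // 0: key == forward substring; 1: key == its reverse complement
  uint64_t key;
};

static void scan_sequence(const char* s, size_t n, int k, int w,
                          std::vector<ScanHit>& out) {
  if (n < (size_t)k) return;
  size_t npos = n - (size_t)k + 1;

  std::vector<uint64_t> canon_hash(npos), canon_key(npos);
  std::vector<uint8_t> orient(npos), valid(npos, 0);

  uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;  // consecutive unambiguous bases ending at current position
  for (size_t i = 0; i < n; ++i) {
    int c = base2code(s[i]);
    if (c < 0) {
      run = 0;
      fwd = rev = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    ++run;
    if (run >= k) {
      size_t pos = i - (size_t)k + 1;
      uint64_t hf = wang_hash64(fwd);
      uint64_t hr = wang_hash64(rev);
      if (hf <= hr) {
        canon_hash[pos] = hf; canon_key[pos] = fwd; orient[pos] = 0;
      } else {
        canon_hash[pos] = hr; canon_key[pos] = rev; orient[pos] = 1;
      }
      valid[pos] = 1;
    }
  }

  std::vector<uint8_t> selected(npos, 0);
  size_t nw;
  size_t wlen;
  if (npos >= (size_t)w) {
    nw = npos - (size_t)w + 1;
    wlen = (size_t)w;
  } else {
    nw = 1;
    wlen = npos;
  }
  for (size_t j = 0; j < nw; ++j) {
    uint64_t mn = UINT64_MAX;
    for (size_t t = j; t < j + wlen; ++t)
      if (valid[t] && canon_hash[t] < mn) mn = canon_hash[t];
    if (mn == UINT64_MAX) continue;
    for (size_t t = j; t < j + wlen; ++t)
      if (valid[t] && canon_hash[t] == mn) selected[t] = 1;
  }
  for (size_t t = 0; t < npos; ++t) {
    if (selected[t]) {
      ScanHit h;
      h.offset = (int)t;
      h.orient = orient[t];
      h.key = canon_key[t];
      out.push_back(h);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_scan_minimizers(std::string seq, int k, int w) {
  if (k < 1 || k > MAX_KMER) stop("k must be in 1..%d", MAX_KMER);
  if (w < 1) stop("w must be >= 1");
  std::vector<ScanHit> hits;
  scan_sequence(seq.c_str(), seq.size(), k, w, hits);
  size_t n = hits.size();
  IntegerVector offset(n), orient(n);
  CharacterVector key(n);
  for (size_t i = 0; i < n; ++i) {
    offset[i] = hits[i].offset;
    orient[i] = hits[i].orient;
    key[i] = u64hex(hits[i].key);
  }
  return DataFrame::create(_["offset"] = offset, _["orient"] = orient,
                           _["key"] = key, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_scan_reads(CharacterVector reads, int k, int w, bool with_ry) {
  if (k < 1 || k > MAX_KMER) stop("k must be in 1..%d", MAX_KMER);
  if (w < 1) stop("w must be >= 1");
  std::vector<int> ridx, offset, orient;
  std::vector<std::string> key, rykey;
  std::vector<ScanHit> hits;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    hits.clear();
    scan_sequence(s, strlen(s), k, w, hits);
    for (size_t j = 0; j < hits.size(); ++j) {
      ridx.push_back((int)i + 1);
      offset.push_back(hits[j].offset);
      orient.push_back(hits[j].orient);
      key.push_back(u64hex(hits[j].key));
      if (with_ry) rykey.push_back(u64hex(project_kmer(hits[j].key, k)));
    }
  }
  if (with_ry)
    return DataFrame::create(_["read"] = ridx, _["offset"] = offset,
                             _["orient"] = orient, _["key"] = wrap(key),
                             _["rykey"] = wrap(rykey),
                             _["stringsAsFactors"] = false);
  return DataFrame::create(_["read"] = ridx, _["offset"] = offset,
                           _["orient"] = orient, _["key"] = wrap(key),
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// seed comparison: per-pair transition-mismatch records

// [[Rcpp::export]]
List cpp_compare_keys(CharacterVector a, CharacterVector b, int k) {
  R_xlen_t n = a.size();
  IntegerVector m(n);
  std::vector<int> pair, pos;
  std::vector<char> abase, bbase;
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t xa = hex2u64(CHAR(STRING_ELT(a, i)));
    uint64_t xb = hex2u64(CHAR(STRING_ELT(b, i)));
    int cnt = 0;
    for (int j = 0; j < k; ++j) {
      int shift = 2 * (k - 1 - j);  // j is position from the 5' end of the kmer
      int ca = (int)((xa >> shift) & 3ULL);
      int cb = (int)((xb >> shift) & 3ULL);
      if (ca != cb) {
        ++cnt;
        pair.push_back((int)i + 1);
        pos.push_back(j);
        abase.push_back(CODE2BASE[ca]);
        bbase.push_back(CODE2BASE[cb]);
      }
    }
    m[i] = cnt;
  }
  size_t nm = pair.size();
  CharacterVector av(nm), bv(nm);
  for (size_t i = 0; i < nm; ++i) {
    av[i] = std::string(1, abase[i]);
    bv[i] = std::string(1, bbase[i]);
  }
  return List::create(_["m"] = m, _["pair"] = wrap(pair), _["pos"] = wrap(pos),
                      _["a_base"] = av, _["b_base"] = bv);
}

// ---------------------------------------------------------------------------
// alignment extension
//
// Gapless bidirectional X-drop from the cluster anchor; if the read is fully
// covered the gapless alignment is kept, otherwise a banded gapped fitting
// alignment around the cluster diagonal is computed (affine gaps).

struct ExtResult {
  bool ok;
  bool gapless;
  double start;
  int score;
  int nm;
  std::string cigar;
};

static void push_op(std::string& cig, std::vector<std::pair<int,char> >& ops,
                    char op) {
  if (!ops.empty() && ops.back().second == op) ops.back().first++;
  else ops.push_back(std::make_pair(1, op));
  (void)cig;
}

static std::string ops_to_cigar(const std::vector<std::pair<int,char> >& ops) {
  std::string out;
  char buf[16];
  for (size_t i = 0; i < ops.size(); ++i) {
    snprintf(buf, sizeof(buf), "%d%c", ops[i].first, ops[i].second);
    out += buf;
  }
  return out;
}

static ExtResult extend_one(const char* read, int L, const char* ref,
                            long refLen, long start0, int anchorRead,
                            int match, int mismatch, int gapOpen,
                            int gapExtend, int xdrop, int band) {
  ExtResult res;
  res.ok = false; res.gapless = false; res.start = 0; res.score = 0; res.nm = 0;

  if (start0 < 0 || start0 + L > refLen) return res;  // read falls off the panel

  // gapless bidirectional X-drop along the anchor diagonal
  int total = 0, nmis = 0;
  bool covered = true;
  {
    int best = 0, cur = 0;
    for (int i = anchorRead; i < L; ++i) {  // rightward including anchor base
      char rb = read[i];
      char gb = ref[start0 + i];
      int s = (rb == gb && rb != 'N') ? match : -mismatch;
      cur += s;
      total += s;
      if (s < 0) ++nmis;
      if (cur > best) best = cur;
      if (cur < best - xdrop) { covered = false; break; }
    }
    best = 0; cur = 0;
    for (int i = anchorRead - 1; covered && i >= 0; --i) {  // leftward
      char rb = read[i];
      char gb = ref[start0 + i];
      int s = (rb == gb && rb != 'N') ? match : -mismatch;
      cur += s;
      total += s;
      if (s < 0) ++nmis;
      if (cur > best) best = cur;
      if (cur < best - xdrop) { covered = false; break; }
    }
  }
  if (covered) {
    res.ok = true;
    res.gapless = true;
    res.start = (double)start0;
    res.score = total;
    res.nm = nmis;
    std::vector<std::pair<int,char> > ops;
    ops.push_back(std::make_pair(L, 'M'));
    res.cigar = ops_to_cigar(ops);
    return res;
  }

  // banded gapped fitting alignment: read global, ref-window end gaps free
  long ws = start0 - band; if (ws < 0) ws = 0;
  long we = start0 + L + band; if (we > refLen) we = refLen;
  int S = (int)(we - ws);
  if (S < 1) return res;

  const int NEG = -1000000;
  int W = S + 1;
  std::vector<int> M((L + 1) * W, NEG), Ix((L + 1) * W, NEG),
      Iy((L + 1) * W, NEG);
  // trace: 2 bits per matrix
  std::vector<uint8_t> tM((L + 1) * W, 0), tIx((L + 1) * W, 0),
      tIy((L + 1) * W, 0);

  for (int j = 0; j <= S; ++j) M[j] = 0;  // free leading reference gap
  for (int i = 1; i <= L; ++i)
    Ix[i * W] = -(gapOpen + i * gapExtend);

  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= S; ++j) {
      int idx = i * W + j;
      char rb = read[i - 1];
      char gb = ref[ws + j - 1];
      int sub = (rb == gb && rb != 'N') ? match : -mismatch;
      int d = idx - W - 1;
      // M: diagonal move from best of three
      int bm = M[d], src = 0;
      if (Ix[d] > bm) { bm = Ix[d]; src = 1; }
      if (Iy[d] > bm) { bm = Iy[d]; src = 2; }
      if (bm > NEG / 2) { M[idx] = bm + sub; tM[idx] = (uint8_t)src; }
      // Ix: consume read (insertion w.r.t. reference)
      int up = idx - W;
      int openx = M[up] > NEG / 2 ? M[up] - gapOpen - gapExtend : NEG;
      int extx = Ix[up] > NEG / 2 ? Ix[up] - gapExtend : NEG;
      if (openx >= extx) { Ix[idx] = openx; tIx[idx] = 0; }
      else { Ix[idx] = extx; tIx[idx] = 1; }
      // Iy: consume reference (deletion)
      int lf = idx - 1;
      int openy = M[lf] > NEG / 2 ? M[lf] - gapOpen - gapExtend : NEG;
      int exty = Iy[lf] > NEG / 2 ? Iy[lf] - gapExtend : NEG;
      if (openy >= exty) { Iy[idx] = openy; tIy[idx] = 0; }
      else { Iy[idx] = exty; tIy[idx] = 1; }
    }
  }

  // best over the last read row (trailing reference free); ties to leftmost
  int bestScore = NEG, bestJ = -1, bestMat = 0;
  for (int j = 0; j <= S; ++j) {
    int idx = L * W + j;
    if (M[idx] > bestScore) { bestScore = M[idx]; bestJ = j; bestMat = 0; }
    if (Ix[idx] > bestScore) { bestScore = Ix[idx]; bestJ = j; bestMat = 1; }
  }
  if (bestJ < 0 || bestScore <= NEG / 2) return res;

  // traceback
  std::vector<std::pair<int,char> > rops;
  int i = L, j = bestJ, mat = bestMat;
  int nmg = 0;
  std::string dummy;
  while (i > 0) {
    int idx = i * W + j;
    if (mat == 0) {
      char rb = read[i - 1];
      char gb = ref[ws + j - 1];
      if (!(rb == gb && rb != 'N')) ++nmg;
      push_op(dummy, rops, 'M');
      mat = tM[idx];
      --i; --j;
    } else if (mat == 1) {
      push_op(dummy, rops, 'I');
      ++nmg;
      int prev = tIx[idx];
      --i;
      mat = prev == 0 ? 0 : 1;
    } else {
      push_op(dummy, rops, 'D');
      ++nmg;
      int prev = tIy[idx];
      --j;
      mat = prev == 0 ? 0 : 2;
    }
  }
  std::vector<std::pair<int,char> > ops(rops.rbegin(), rops.rend());
  // merge adjacent equal ops after reversal
  std::vector<std::pair<int,char> > merged;
  for (size_t t = 0; t < ops.size(); ++t) {
    if (!merged.empty() && merged.back().second == ops[t].second)
      merged.back().first += ops[t].first;
    else merged.push_back(ops[t]);
  }

  res.ok = true;
  res.gapless = false;
  res.start = (double)(ws + j);
  res.score = bestScore;
  res.nm = nmg;
  res.cigar = ops_to_cigar(merged);
  return res;
}

// [[Rcpp::export]]
DataFrame cpp_extend_batch(CharacterVector readSeq, IntegerVector refIdx,
                           CharacterVector refSeqs, NumericVector anchorRef,
                           IntegerVector anchorRead, int match, int mismatch,
                           int gapOpen, int gapExtend, int xdrop, int band) {
  R_xlen_t n = readSeq.size();
  LogicalVector ok(n), gapless(n);
  NumericVector start(n);
  IntegerVector score(n), nm(n);
  CharacterVector cigar(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* rd = CHAR(STRING_ELT(readSeq, i));
    int L = (int)strlen(rd);
    const char* rf = CHAR(STRING_ELT(refSeqs, refIdx[i] - 1));
    long refLen = (long)strlen(rf);
    long start0 = (long)anchorRef[i] - (long)anchorRead[i];
    ExtResult r = extend_one(rd, L, rf, refLen, start0, anchorRead[i], match,
                             mismatch, gapOpen, gapExtend, xdrop, band);
    ok[i] = r.ok;
    gapless[i] = r.gapless;
    start[i] = r.start;
    score[i] = r.score;
    nm[i] = r.nm;
    cigar[i] = r.cigar;
  }
  return DataFrame::create(_["ok"] = ok, _["gapless"] = gapless,
                           _["start"] = start, _["score"] = score,
                           _["nm"] = nm, _["cigar"] = cigar,
                           _["stringsAsFactors"] = false);
}

// rescore an edit script against the reference (oracle support): returns
// score and NM recomputed by walking the CIGAR
// [[Rcpp::export]]
List cpp_rescore_cigar(std::string read, std::string ref, double start0,
                       std::string cigar, int match, int mismatch, int gapOpen,
                       int gapExtend) {
  long i = 0, j = (long)start0;
  long score = 0, nm = 0, consumed = 0;
  size_t p = 0;
  while (p < cigar.size()) {
    long len = 0;
    while (p < cigar.size() && isdigit(cigar[p])) len = len * 10 + (cigar[p++] - '0');
    char op = cigar[p++];
    if (op == 'M') {
      for (long t = 0; t < len; ++t) {
        char rb = read[i + t];
        char gb = ref[j + t];
        if (rb == gb && rb != 'N') score += match;
        else { score -= mismatch; ++nm; }
      }
      i += len; j += len; consumed += len;
    } else if (op == 'I') {
      score -= gapOpen + len * gapExtend;
      nm += len; i += len; consumed += len;
    } else if (op == 'D') {
      score -= gapOpen + len * gapExtend;
      nm += len; j += len;
    } else {
      stop("unsupported CIGAR op '%c'", op);
    }
  }
  return List::create(_["score"] = (double)score, _["nm"] = (double)nm,
                      _["read_consumed"] = (double)consumed);
}

// ---------------------------------------------------------------------------
// damage application (simulator) — uses R's RNG so set.seed() governs it

// [[Rcpp::export]]
List cpp_apply_damage(CharacterVector frags, NumericVector ct5,
                      NumericVector ga3, NumericVector ct3, bool ss) {
  RNGScope scope;
  int d5 = ct5.size(), d3 = ga3.size(), dct3 = ct3.size();
  R_xlen_t n = frags.size();
  CharacterVector out(n);
  std::vector<int> eread, epos;
  std::vector<char> eref, eobs;
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(frags, i));
    int L = (int)strlen(s);
    buf.assign(s, L);
    for (int p = 0; p < L; ++p) {
      char b = buf[p];
      int p5 = p, p3 = L - 1 - p;
      if (b == 'C') {
        double r5 = d5 > 0 ? ct5[p5 < d5 ? p5 : d5 - 1] : 0.0;
        double rate = r5;
        if (ss && dct3 > 0) {
          double r3 = ct3[p3 < dct3 ? p3 : dct3 - 1];
          rate = 1.0 - (1.0 - r5) * (1.0 - r3);
        }
        if (rate > 0 && unif_rand() < rate) {
          buf[p] = 'T';
          eread.push_back((int)i + 1); epos.push_back(p);
          eref.push_back('C'); eobs.push_back('T');
        }
      } else if (b == 'G') {
        double rate = d3 > 0 ? ga3[p3 < d3 ? p3 : d3 - 1] : 0.0;
        if (rate > 0 && unif_rand() < rate) {
          buf[p] = 'A';
          eread.push_back((int)i + 1); epos.push_back(p);
          eref.push_back('G'); eobs.push_back('A');
        }
      }
    }
    out[i] = buf;
  }
  size_t ne = eread.size();
  CharacterVector refv(ne), obsv(ne);
  for (size_t t = 0; t < ne; ++t) {
    refv[t] = std::string(1, eref[t]);
    obsv[t] = std::string(1, eobs[t]);
  }
  return List::create(_["seq"] = out,
                      _["events"] = DataFrame::create(
                          _["read"] = wrap(eread), _["pos"] = wrap(epos),
                          _["ref_base"] = refv, _["read_base"] = obsv,
                          _["stringsAsFactors"] = false));
}

// [[Rcpp::export]]
CharacterVector cpp_random_dna(IntegerVector lens, double gc) {
  RNGScope scope;
  R_xlen_t n = lens.size();
  CharacterVector out(n);
  std::string buf;
  double pg = gc / 2.0, pc = gc / 2.0, pa = (1.0 - gc) / 2.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int L = lens[i];
    buf.assign(L, 'A');
    for (int j = 0; j < L; ++j) {
      double u = unif_rand();
      if (u < pa) buf[j] = 'A';
      else if (u < 2 * pa) buf[j] = 'T';
      else if (u < 2 * pa + pc) buf[j] = 'C';
      else { (void)pg; buf[j] = 'G'; }
    }
    out[i] = buf;
  }
  return out;
}

// ---------------------------------------------------------------------------
// substitution counting for damage-profile estimation
//
// Inputs are SAM-style records: SEQ in reference-forward orientation, POS
// 0-based, CIGAR over M/I/D. Reverse-strand records are complemented and
// reversed before counting so positions are measured on the sequenced strand.

// [[Rcpp::export]]
List cpp_damage_counts(CharacterVector readSeqs, IntegerVector refIdx,
                       CharacterVector refSeqs, NumericVector pos0,
                       CharacterVector cigars, LogicalVector revStrand,
                       int depth) {
  // counts[end][pos][from*4+to], opps[end][pos][from]
  IntegerVector counts(Dimension(2, depth, 16));
  IntegerVector opps(Dimension(2, depth, 4));
  auto baseidx = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  std::vector<char> rb, gb;
  for (R_xlen_t rIdx = 0; rIdx < readSeqs.size(); ++rIdx) {
    const char* rd = CHAR(STRING_ELT(readSeqs, rIdx));
    const char* rf = CHAR(STRING_ELT(refSeqs, refIdx[rIdx] - 1));
    long refLen = (long)strlen(rf);
    const char* cg = CHAR(STRING_ELT(cigars, rIdx));
    long i = 0, j = (long)pos0[rIdx];
    rb.clear(); gb.clear();
    size_t p = 0; size_t cl = strlen(cg);
    bool bad = false;
    while (p < cl) {
      long len = 0;
      while (p < cl && isdigit(cg[p])) len = len * 10 + (cg[p++] - '0');
      if (p >= cl) { bad = true; break; }
      char op = cg[p++];
      if (op == 'M') {
        for (long t = 0; t < len; ++t) {
          if (j + t < 0 || j + t >= refLen) { bad = true; break; }
          rb.push_back(rd[i + t]);
          gb.push_back(rf[j + t]);
        }
        i += len; j += len;
      } else if (op == 'I' || op == 'S') {
        i += len;
      } else if (op == 'D') {
        j += len;
      } else { bad = true; break; }
      if (bad) break;
    }
    if (bad) continue;
    int L = (int)rb.size();
    if (revStrand[rIdx]) {  // back to sequenced-read orientation
      std::reverse(rb.begin(), rb.end());
      std::reverse(gb.begin(), gb.end());
      for (int t = 0; t < L; ++t) {
        rb[t] = comp_base(rb[t]);
        gb[t] = comp_base(gb[t]);
      }
    }
    for (int t = 0; t < L; ++t) {
      int from = baseidx(gb[t]);
      int to = baseidx(rb[t]);
      if (from < 0 || to < 0) continue;
      int p5 = t, p3 = L - 1 - t;
      if (p5 < depth) {
        opps[0 + 2 * (p5 + depth * from)] += 1;
        if (from != to) counts[0 + 2 * (p5 + depth * (from * 4 + to))] += 1;
      }
      if (p3 < depth) {
        opps[1 + 2 * (p3 + depth * from)] += 1;
        if (from != to) counts[1 + 2 * (p3 + depth * (from * 4 + to))] += 1;
      }
    }
  }
  return List::create(_["counts"] = counts, _["opps"] = opps);
}
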