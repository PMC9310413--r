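#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small helpers
// ---------------------------------------------------------------------------

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static void putVarint(std::vector<uint8_t>& out, uint64_t v) {
  while (v >= 0x80u) {
    out.push_back(static_cast<uint8_t>(v & 0x7fu) | 0x80u);
    v >>= 7;
  }
  out.push_back(static_cast<uint8_t>(v));
}

static uint64_t getVarint(const uint8_t* buf, size_t n, size_t& pos) {
  uint64_t v = 0;
  int shift = 0;
  for (;;) {
    if (pos >= n) stop("corrupt stream: truncated varint");
    uint8_t b = buf[pos++];
    v |= static_cast<uint64_t>(b & 0x7fu) << shift;
    if (!(b & 0x80u)) break;
    shift += 7;
    if (shift > 63) stop("corrupt stream: varint overflow");
  }
  return v;
}

static inline uint64_t zigzagEnc(int64_t v) {
  return (static_cast<uint64_t>(v) << 1) ^ static_cast<uint64_t>(v >> 63);
}
static inline int64_t zigzagDec(uint64_t v) {
  return static_cast<int64_t>(v >> 1) ^ -static_cast<int64_t>(v & 1);
}

// ---------------------------------------------------------------------------
// varint vectors (zigzag optional) — archive plumbing
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_encode_varints(NumericVector x, bool zigzag) {
  std::vector<uint8_t> out;
  out.reserve(x.size() * 2);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double d = x[i];
    if (NumericVector::is_na(d)) stop("cannot varint-encode NA");
    int64_t v = static_cast<int64_t>(d);
    if (static_cast<double>(v) != d) stop("cannot varint-encode non-integer value");
    uint64_t u;
    if (zigzag) {
      u = zigzagEnc(v);
    } else {
      if (v < 0) stop("negative value in unsigned varint encoding");
      u = static_cast<uint64_t>(v);
    }
    putVarint(out, u);
  }
  return RawVector(out.begin(), out.end());
}

// offset is 0-based; returns list(values, offset) with the new 0-based offset
// [[Rcpp::export]]
List cpp_decode_varints(RawVector r, double offset, int n, bool zigzag) {
  const uint8_t* buf = RAW(r);
  size_t len = r.size();
  size_t pos = static_cast<size_t>(offset);
  if (pos > len) stop("corrupt stream: offset beyond end");
  NumericVector vals(n);
  for (int i = 0; i < n; ++i) {
    uint64_t u = getVarint(buf, len, pos);
    vals[i] = zigzag ? static_cast<double>(zigzagDec(u)) : static_cast<double>(u);
  }
  return List::create(_["values"] = vals, _["offset"] = static_cast<double>(pos));
}

// ---------------------------------------------------------------------------
// 2-bit base packing
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_pack_bases(std::string s) {
  size_t n = s.size();
  RawVector out((n + 3) / 4);
  uint8_t* p = RAW(out);
  std::fill(p, p + out.size(), 0);
  for (size_t i = 0; i < n; ++i) {
    int c = baseCode(s[i]);
    if (c < 0) stop("non-ACGT symbol in base stream");
    p[i >> 2] |= static_cast<uint8_t>(c << ((i & 3) << 1));
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_unpack_bases(RawVector r, double n) {
  size_t len = static_cast<size_t>(n);
  if (r.size() < static_cast<R_xlen_t>((len + 3) / 4))
    stop("corrupt stream: packed base block too short");
  std::string s(len, 'A');
  const uint8_t* p = RAW(r);
  for (size_t i = 0; i < len; ++i)
    s[i] = CODE2BASE[(p[i >> 2] >> ((i & 3) << 1)) & 3];
  return s;
}

// ---------------------------------------------------------------------------
// FNV-1a 64-bit content fingerprint
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_fnv64(RawVector data) {
  uint64_t h = 0xcbf29ce484222325ULL;
  const uint8_t* p = RAW(data);
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    h ^= p[i];
    h *= 0x100000001b3ULL;
  }
  RawVector out(8);
  for (int i = 0; i < 8; ++i) out[i] = static_cast<uint8_t>((h >> (8 * i)) & 0xff);
  return out;
}

// ---------------------------------------------------------------------------
// k-mer index of the reference base stream
// ---------------------------------------------------------------------------

struct KIndex {
  int k;
  std::string ref;
  std::unordered_map<uint64_t, std::vector<int>> pos;
  double total;  // stored position count (after any occurrence cap)
};

static uint64_t encodeKmer(const char* s, int k) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int c = baseCode(s[i]);
    if (c < 0) stop("non-ACGT symbol in k-mer");
    code = (code << 2) | static_cast<uint64_t>(c);
  }
  return code;
}

// [[Rcpp::export]]
SEXP cpp_build_kmer_index(std::string ref, int k, double max_occ) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  for (size_t i = 0; i < ref.size(); ++i)
    if (baseCode(ref[i]) < 0) stop("reference base stream contains non-ACGT symbol");
  XPtr<KIndex> xp(new KIndex(), true);
  xp->k = k;
  xp->ref = ref;
  xp->total = 0;
  long n = static_cast<long>(ref.size());
  if (n >= k) {
    size_t nk = static_cast<size_t>(n - k + 1);
    xp->pos.reserve(nk * 5 / 4 + 16);
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t code = 0;
    for (long i = 0; i < n; ++i) {
      code = ((code << 2) | static_cast<uint64_t>(baseCode(xp->ref[i]))) & mask;
      if (i >= k - 1) {
        std::vector<int>& v = xp->pos[code];
        if (R_finite(max_occ) && static_cast<double>(v.size()) >= max_occ) continue;
        v.push_back(static_cast<int>(i - k + 1));
        xp->total += 1;
      }
    }
  }
  return xp;
}

// [[Rcpp::export]]
List cpp_kmer_index_info(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  return List::create(_["k"] = xp->k,
                      _["ref_length"] = static_cast<double>(xp->ref.size()),
                      _["n_positions"] = xp->total,
                      _["n_kmers"] = static_cast<double>(xp->pos.size()));
}

// [[Rcpp::export]]
IntegerVector cpp_kmer_lookup(SEXP xp_, std::string kmer) {
  XPtr<KIndex> xp(xp_);
  if (static_cast<int>(kmer.size()) != xp->k) stop("query length does not equal index k");
  uint64_t code = encodeKmer(kmer.c_str(), xp->k);
  auto it = xp->pos.find(code);
  if (it == xp->pos.end()) return IntegerVector(0);
  return IntegerVector(it->second.begin(), it->second.end());
}

// [[Rcpp::export]]
std::string cpp_kmer_index_ref(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  return xp->ref;
}

// ---------------------------------------------------------------------------
// first-order greedy matcher
// ---------------------------------------------------------------------------

// Greedy longest-match against the indexed reference. At each cursor the
// anchor k-mer is looked up; every candidate occurrence is extended as far as
// the exact match runs. The longest extension wins; ties go to the candidate
// whose start has the smallest absolute delta to the previous match's end,
// then to the smallest position (keeps encoded deltas small).
// [[Rcpp::export]]
List cpp_compress_first_order(SEXP xp_, std::string target) {
  XPtr<KIndex> xp(xp_);
  const int k = xp->k;
  const std::string& ref = xp->ref;
  const long rn = static_cast<long>(ref.size());
  const long tn = static_cast<long>(target.size());
  for (long i = 0; i < tn; ++i)
    if (baseCode(target[i]) < 0) stop("target base stream contains non-ACGT symbol");

  std::vector<int> type, pos, len;
  std::vector<std::string> lit;
  long litStart = -1;
  long prevEnd = 0;  // reference end of the previous match
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  long c = 0;
  bool haveCode = false;
  uint64_t code = 0;
  while (c < tn) {
    int bestLen = -1, bestPos = -1;
    if (c + k <= tn) {
      if (!haveCode) {
        code = encodeKmer(target.c_str() + c, k);
        haveCode = true;
      }
      auto it = xp->pos.find(code);
      if (it != xp->pos.end()) {
        int64_t bestDelta = 0;
        for (int p : it->second) {
          long l = k;
          while (p + l < rn && c + l < tn && ref[p + l] == target[c + l]) ++l;
          int64_t delta = static_cast<int64_t>(p) - prevEnd;
          if (delta < 0) delta = -delta;
          if (l > bestLen || (l == bestLen && (delta < bestDelta ||
                              (delta == bestDelta && p < bestPos)))) {
            bestLen = static_cast<int>(l);
            bestPos = p;
            bestDelta = delta;
          }
        }
      }
    }
    if (bestLen >= k) {
      if (litStart >= 0) {
        type.push_back(1); pos.push_back(NA_INTEGER);
        len.push_back(static_cast<int>(c - litStart));
        lit.push_back(target.substr(litStart, c - litStart));
        litStart = -1;
      }
      type.push_back(0); pos.push_back(bestPos); len.push_back(bestLen);
      lit.push_back("");
      prevEnd = bestPos + bestLen;
      c += bestLen;
      haveCode = false;
    } else {
      if (litStart < 0) litStart = c;
      ++c;
      if (haveCode && c + k <= tn) {
        code = ((code << 2) | static_cast<uint64_t>(baseCode(target[c + k - 1]))) & mask;
      } else {
        haveCode = false;
      }
    }
  }
  if (litStart >= 0) {
    type.push_back(1); pos.push_back(NA_INTEGER);
    len.push_back(static_cast<int>(tn - litStart));
    lit.push_back(target.substr(litStart, tn - litStart));
  }

  R_xlen_t nt = type.size();
  CharacterVector litv(nt);
  for (R_xlen_t i = 0; i < nt; ++i) {
    if (type[i] == 0) litv[i] = NA_STRING; else litv[i] = lit[i];
  }
  return List::create(_["type"] = IntegerVector(type.begin(), type.end()),
                      _["pos"] = IntegerVector(pos.begin(), pos.end()),
                      _["len"] = IntegerVector(len.begin(), len.end()),
                      _["lit"] = litv);
}

// [[Rcpp::export]]
std::string cpp_decompress_first_order(std::string ref, IntegerVector type,
                                       IntegerVector pos, IntegerVector len,
                                       CharacterVector lit) {
  long rn = static_cast<long>(ref.size());
  long total = 0;
  for (R_xlen_t i = 0; i < type.size(); ++i) total += len[i];
  std::string out;
  out.reserve(total);
  for (R_xlen_t i = 0; i < type.size(); ++i) {
    if (type[i] == 0) {
      long p = pos[i], l = len[i];
      if (p < 0 || l < 0 || p + l > rn)
        stop("corrupt stream: first-order match outside reference bounds");
      out.append(ref, p, l);
    } else {
      out.append(as<std::string>(lit[i]));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// second-order token index and matcher
// ---------------------------------------------------------------------------

struct SOTok {
  int type;  // 0 match, 1 literal
  int pos;
  int len;
  std::string lit;
};

struct SOIndex {
  std::vector<int> seqIds;
  std::vector<std::vector<SOTok>> refs;
  // fingerprint -> (ref slot, token position), in insertion order
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> map;
  // token-pair fingerprint -> same locations; any accepted run of >= 2
  // tokens must start at a pair hit, so for min_run >= 2 the matcher scans
  // this much sparser map instead (identical result, fewer candidates)
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> pairMap;
  double nLocations = 0;
};

static std::string tokKey(const SOTok& t) {
  if (t.type == 0)
    return "M:" + std::to_string(t.pos) + "," + std::to_string(t.len);
  return "L:" + t.lit;
}

static inline bool tokEq(const SOTok& a, const SOTok& b) {
  if (a.type != b.type) return false;
  if (a.type == 0) return a.pos == b.pos && a.len == b.len;
  return a.lit == b.lit;
}

static std::vector<SOTok> toToks(IntegerVector type, IntegerVector pos,
                                 IntegerVector len, CharacterVector lit) {
  std::vector<SOTok> v(type.size());
  for (R_xlen_t i = 0; i < type.size(); ++i) {
    v[i].type = type[i];
    v[i].pos = (type[i] == 0) ? pos[i] : 0;
    v[i].len = len[i];
    v[i].lit = (type[i] == 1) ? as<std::string>(lit[i]) : std::string();
  }
  return v;
}

// [[Rcpp::export]]
SEXP cpp_token_index_new() {
  XPtr<SOIndex> xp(new SOIndex(), true);
  return xp;
}

// [[Rcpp::export]]
void cpp_token_index_add(SEXP xp_, int seqId, IntegerVector type,
                         IntegerVector pos, IntegerVector len,
                         CharacterVector lit) {
  XPtr<SOIndex> xp(xp_);
  if (!xp->seqIds.empty() && seqId <= xp->seqIds.back())
    stop("second-order references must be added in increasing seq_id order");
  int slot = static_cast<int>(xp->refs.size());
  xp->seqIds.push_back(seqId);
  xp->refs.push_back(toToks(type, pos, len, lit));
  const std::vector<SOTok>& toks = xp->refs.back();
  for (size_t i = 0; i < toks.size(); ++i) {
    xp->map[tokKey(toks[i])].push_back({slot, static_cast<int>(i)});
    xp->nLocations += 1;
    if (i + 1 < toks.size())
      xp->pairMap[tokKey(toks[i]) + "|" + tokKey(toks[i + 1])]
          .push_back({slot, static_cast<int>(i)});
  }
}

// [[Rcpp::export]]
List cpp_token_index_info(SEXP xp_) {
  XPtr<SOIndex> xp(xp_);
  return List::create(_["n_refs"] = static_cast<int>(xp->refs.size()),
                      _["seq_ids"] = IntegerVector(xp->seqIds.begin(), xp->seqIds.end()),
                      _["n_locations"] = xp->nLocations);
}

// returns a 2-column matrix (ref seq_id, token position), possibly 0-row
// [[Rcpp::export]]
IntegerMatrix cpp_token_index_lookup(SEXP xp_, int type, int pos, int len,
                                     std::string lit) {
  XPtr<SOIndex> xp(xp_);
  SOTok t;
  t.type = type; t.pos = (type == 0) ? pos : 0; t.len = len;
  t.lit = (type == 1) ? lit : std::string();
  auto it = xp->map.find(tokKey(t));
  if (it == xp->map.end()) return IntegerMatrix(0, 2);
  IntegerMatrix out(it->second.size(), 2);
  for (size_t i = 0; i < it->second.size(); ++i) {
    out(i, 0) = xp->seqIds[it->second[i].first];
    out(i, 1) = it->second[i].second;
  }
  return out;
}

// Greedy token-run matcher. At each target token the fingerprint is looked
// up; each candidate location is extended over exactly-equal consecutive
// tokens; the longest run wins (ties: lowest ref seq_id, then lowest token
// position — the insertion-order scan with strict improvement gives this).
// Runs shorter than min_run become Passthrough tokens.
// [[Rcpp::export]]
List cpp_compress_second_order(SEXP xp_, IntegerVector type, IntegerVector pos,
                               IntegerVector len, CharacterVector lit,
                               int min_run) {
  XPtr<SOIndex> xp(xp_);
  std::vector<SOTok> tgt = toToks(type, pos, len, lit);
  long T = static_cast<long>(tgt.size());

  std::vector<int> kind, refId, tokPos, tokCount, foType, foPos, foLen;
  std::vector<std::string> foLit;

  const bool usePairs = min_run >= 2;
  long t = 0;
  while (t < T) {
    const std::vector<std::pair<int, int>>* cands = nullptr;
    if (usePairs) {
      if (t + 1 < T) {
        auto it = xp->pairMap.find(tokKey(tgt[t]) + "|" + tokKey(tgt[t + 1]));
        if (it != xp->pairMap.end()) cands = &it->second;
      }
    } else {
      auto it = xp->map.find(tokKey(tgt[t]));
      if (it != xp->map.end()) cands = &it->second;
    }
    int bestRun = 0, bestSlot = -1, bestTp = -1;
    if (cands != nullptr) {
      for (const auto& loc : *cands) {
        const std::vector<SOTok>& rtoks = xp->refs[loc.first];
        long run = 0;
        while (t + run < T &&
               static_cast<size_t>(loc.second + run) < rtoks.size() &&
               tokEq(tgt[t + run], rtoks[loc.second + run]))
          ++run;
        if (run > bestRun) {
          bestRun = static_cast<int>(run);
          bestSlot = loc.first;
          bestTp = loc.second;
        }
      }
    }
    if (bestRun >= min_run) {
      kind.push_back(0);
      refId.push_back(xp->seqIds[bestSlot]);
      tokPos.push_back(bestTp);
      tokCount.push_back(bestRun);
      foType.push_back(NA_INTEGER); foPos.push_back(NA_INTEGER);
      foLen.push_back(NA_INTEGER); foLit.push_back("");
      t += bestRun;
    } else {
      kind.push_back(1);
      refId.push_back(NA_INTEGER); tokPos.push_back(NA_INTEGER);
      tokCount.push_back(NA_INTEGER);
      foType.push_back(tgt[t].type);
      foPos.push_back(tgt[t].type == 0 ? tgt[t].pos : NA_INTEGER);
      foLen.push_back(tgt[t].len);
      foLit.push_back(tgt[t].lit);
      t += 1;
    }
  }

  R_xlen_t n = kind.size();
  CharacterVector litv(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (kind[i] == 1 && foType[i] == 1) litv[i] = foLit[i]; else litv[i] = NA_STRING;
  }
  return List::create(_["kind"] = IntegerVector(kind.begin(), kind.end()),
                      _["refId"] = IntegerVector(refId.begin(), refId.end()),
                      _["tokPos"] = IntegerVector(tokPos.begin(), tokPos.end()),
                      _["tokCount"] = IntegerVector(tokCount.begin(), tokCount.end()),
                      _["foType"] = IntegerVector(foType.begin(), foType.end()),
                      _["foPos"] = IntegerVector(foPos.begin(), foPos.end()),
                      _["foLen"] = IntegerVector(foLen.begin(), foLen.end()),
                      _["foLit"] = litv);
}

// ---------------------------------------------------------------------------
// second-order stream (de)serialization
//
// layout: varint token count | 2-bit tag bytes (0 RefMatch, 1 pass Match,
// 2 pass Literal) | per-token payload varints | varint total literal bases |
// 2-bit packed literal bases. Pass-Match positions are zigzag deltas against
// the previous pass-Match's end.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_serialize_so(IntegerVector kind, IntegerVector refId,
                           IntegerVector tokPos, IntegerVector tokCount,
                           IntegerVector foType, IntegerVector foPos,
                           IntegerVector foLen, CharacterVector foLit) {
  R_xlen_t n = kind.size();
  std::vector<uint8_t> out;
  putVarint(out, static_cast<uint64_t>(n));
  // tags
  size_t tagStart = out.size();
  out.resize(tagStart + (n + 3) / 4, 0);
  std::string allLit;
  for (R_xlen_t i = 0; i < n; ++i) {
    int tag;
    if (kind[i] == 0) tag = 0;
    else if (foType[i] == 0) tag = 1;
    else tag = 2;
    out[tagStart + (i >> 2)] |= static_cast<uint8_t>(tag << ((i & 3) << 1));
  }
  int64_t prevEnd = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (kind[i] == 0) {
      putVarint(out, static_cast<uint64_t>(refId[i]));
      putVarint(out, static_cast<uint64_t>(tokPos[i]));
      putVarint(out, static_cast<uint64_t>(tokCount[i]));
    } else if (foType[i] == 0) {
      putVarint(out, zigzagEnc(static_cast<int64_t>(foPos[i]) - prevEnd));
      putVarint(out, static_cast<uint64_t>(foLen[i]));
      prevEnd = static_cast<int64_t>(foPos[i]) + foLen[i];
    } else {
      putVarint(out, static_cast<uint64_t>(foLen[i]));
      allLit += as<std::string>(foLit[i]);
    }
  }
  putVarint(out, static_cast<uint64_t>(allLit.size()));
  size_t litStart = out.size();
  out.resize(litStart + (allLit.size() + 3) / 4, 0);
  for (size_t i = 0; i < allLit.size(); ++i) {
    int c = baseCode(allLit[i]);
    if (c < 0) stop("non-ACGT symbol in literal");
    out[litStart + (i >> 2)] |= static_cast<uint8_t>(c << ((i & 3) << 1));
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_deserialize_so(RawVector r) {
  const uint8_t* buf = RAW(r);
  size_t len = r.size();
  size_t p = 0;
  uint64_t n64 = getVarint(buf, len, p);
  R_xlen_t n = static_cast<R_xlen_t>(n64);
  size_t tagStart = p;
  size_t tagBytes = (n + 3) / 4;
  if (tagStart + tagBytes > len) stop("corrupt stream: truncated tag section");
  p += tagBytes;
  IntegerVector kind(n), refId(n), tokPos(n), tokCount(n), foType(n), foPos(n), foLen(n);
  std::vector<int> tags(n);
  int64_t prevEnd = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int tag = (buf[tagStart + (i >> 2)] >> ((i & 3) << 1)) & 3;
    tags[i] = tag;
    if (tag == 0) {
      kind[i] = 0;
      refId[i] = static_cast<int>(getVarint(buf, len, p));
      tokPos[i] = static_cast<int>(getVarint(buf, len, p));
      tokCount[i] = static_cast<int>(getVarint(buf, len, p));
      foType[i] = NA_INTEGER; foPos[i] = NA_INTEGER; foLen[i] = NA_INTEGER;
    } else if (tag == 1) {
      kind[i] = 1; refId[i] = NA_INTEGER; tokPos[i] = NA_INTEGER; tokCount[i] = NA_INTEGER;
      int64_t d = zigzagDec(getVarint(buf, len, p));
      int64_t l = static_cast<int64_t>(getVarint(buf, len, p));
      foType[i] = 0;
      foPos[i] = static_cast<int>(prevEnd + d);
      foLen[i] = static_cast<int>(l);
      prevEnd = prevEnd + d + l;
    } else if (tag == 2) {
      kind[i] = 1; refId[i] = NA_INTEGER; tokPos[i] = NA_INTEGER; tokCount[i] = NA_INTEGER;
      foType[i] = 1; foPos[i] = NA_INTEGER;
      foLen[i] = static_cast<int>(getVarint(buf, len, p));
    } else {
      stop("corrupt stream: invalid token tag");
    }
  }
  uint64_t totLit = getVarint(buf, len, p);
  size_t litBytes = (static_cast<size_t>(totLit) + 3) / 4;
  if (p + litBytes > len) stop("corrupt stream: truncated literal block");
  CharacterVector foLit(n);
  size_t cursor = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (tags[i] == 2) {
      size_t l = static_cast<size_t>(foLen[i]);
      if (cursor + l > totLit) stop("corrupt stream: literal lengths exceed block");
      std::string s(l, 'A');
      for (size_t j = 0; j < l; ++j) {
        size_t idx = cursor + j;
        s[j] = CODE2BASE[(buf[p + (idx >> 2)] >> ((idx & 3) << 1)) & 3];
      }
      foLit[i] = s;
      cursor += l;
    } else {
      foLit[i] = NA_STRING;
    }
  }
  if (cursor != totLit) stop("corrupt stream: literal block length mismatch");
  return List::create(_["kind"] = kind, _["refId"] = refId, _["tokPos"] = tokPos,
                      _["tokCount"] = tokCount, _["foType"] = foType,
                      _["foPos"] = foPos, _["foLen"] = foLen, _["foLit"] = foLit);
}
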