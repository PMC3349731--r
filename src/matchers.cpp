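// Two independent IUPAC-ambiguity-aware short-read matchers sharing one
// contract: report every alignment of a read against a reference sequence
// with at most `max_sub` substitutions and at most `max_gap` (0 or 1)
// single-base gaps.  An N in a read matches nothing and always costs a
// substitution; an IUPAC code in the reference matches any base in its
// allele set at zero cost.
//
// matcher A ("exhaustive"): banded scan of every offset with early exit.
// matcher B ("seeded"):     pigeonhole seeding (one of 4 read chunks must be
//                           error-free) against a q-gram hash index, with
//                           independent verification at candidate offsets.
// Gap placements tying at equal edit distance collapse to one record per
// (target, offset, strand).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int ref_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 5;
    case 'Y': case 'y': return 10;
    case 'S': case 's': return 6;
    case 'W': case 'w': return 9;
    case 'K': case 'k': return 12;
    case 'M': case 'm': return 3;
    case 'B': case 'b': return 14;
    case 'D': case 'd': return 13;
    case 'H': case 'h': return 11;
    case 'V': case 'v': return 7;
    case 'N': case 'n': return 15;
    default: return 0;
  }
}

// read alphabet: concrete bases only; N (or anything else) matches nothing
static inline int read_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    default: return 0;
  }
}

struct Hit {
  int target;   // 0-based target index
  int offset;   // 0-based offset in target
  int strand;   // 0 = '+', 1 = '-'
  int subs;
  int gaps;
};

typedef std::vector<int> Masks;

// Best (subs, gaps) alignment of read r at offset o of target t, allowing
// <= max_sub substitutions and <= max_gap one-base gaps.  Returns true and
// fills subs/gaps if an alignment within budget exists.
#define SRNAPOP_MAX_READ 63

static bool align_at(const Masks &r, const Masks &t, int o,
                     int max_sub, int max_gap, int &subs_out, int &gaps_out) {
  const int m = (int)r.size(), L = (int)t.size();
  if (o < 0 || o >= L || m > SRNAPOP_MAX_READ) return false;
  bool found = false;
  int best_subs = 0, best_gaps = 0, best_tot = max_sub + max_gap + 1;

  // forward mismatch prefix F[i] = mismatches of r[0..i) vs t[o..o+i),
  // computed until budget exceeded or reference exhausted
  int flim = std::min(m, L - o);
  int F[SRNAPOP_MAX_READ + 1];
  F[0] = 0;
  int fstop = 0;  // last computed index
  for (int i = 0; i < flim; ++i) {
    F[i + 1] = F[i] + ((r[i] & t[o + i]) ? 0 : 1);
    fstop = i + 1;
    if (F[i + 1] > max_sub) break;
  }

  // gapless
  if (o + m <= L && fstop == m && F[m] <= max_sub) {
    best_subs = F[m]; best_gaps = 0; best_tot = F[m]; found = true;
  }

  if (max_gap >= 1) {
    // insertion in read at position g (read base g unaligned):
    // r[g+1..m) vs t[o+g..o+m-1); needs o+m-1 <= L
    if (o + m - 1 <= L) {
      // Bi[j] = mismatches of r[j..m) vs t[o+j-1..o+m-1), j in [jmin, m]
      int Bi[SRNAPOP_MAX_READ + 1];
      int acc = 0, jmin = m;
      Bi[m] = 0;
      for (int j = m - 1; j >= 1; --j) {
        acc += (r[j] & t[o + j - 1]) ? 0 : 1;
        if (acc > max_sub) break;
        Bi[j] = acc; jmin = j;
      }
      int ghi = std::min(fstop, m - 1);
      for (int g = 0; g <= ghi; ++g) {
        if (F[g] > max_sub) break;
        if (g + 1 < jmin) continue;
        int tot = F[g] + Bi[g + 1];
        if (tot <= max_sub && tot + 1 < best_tot) {
          best_subs = tot; best_gaps = 1; best_tot = tot + 1; found = true;
        }
      }
    }

    // deletion: ref base t[o+g] skipped, g in 1..m-1:
    // r[g..m) vs t[o+g+1..o+m+1); needs o+m+1 <= L
    if (o + m + 1 <= L) {
      int Bd[SRNAPOP_MAX_READ + 1];
      int acc = 0, jmin = m;
      Bd[m] = 0;
      for (int j = m - 1; j >= 1; --j) {
        acc += (r[j] & t[o + j + 1]) ? 0 : 1;
        if (acc > max_sub) break;
        Bd[j] = acc; jmin = j;
      }
      int ghi = std::min(fstop, m - 1);
      for (int g = 1; g <= ghi; ++g) {
        if (F[g] > max_sub) break;
        if (g < jmin) continue;
        int tot = F[g] + Bd[g];
        if (tot <= max_sub && tot + 1 < best_tot) {
          best_subs = tot; best_gaps = 1; best_tot = tot + 1; found = true;
        }
      }
    }
  }

  if (found) { subs_out = best_subs; gaps_out = best_gaps; return true; }
  return false;
}

static Masks to_masks(const std::string &s, bool as_read) {
  Masks v(s.size());
  for (size_t i = 0; i < s.size(); ++i)
    v[i] = as_read ? read_mask(s[i]) : ref_mask(s[i]);
  return v;
}

static Masks revcomp_masks(const Masks &v) {
  Masks r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int m = v[v.size() - 1 - i], c = 0;
    if (m & 1) c |= 8;  // A -> T
    if (m & 8) c |= 1;  // T -> A
    if (m & 2) c |= 4;  // C -> G
    if (m & 4) c |= 2;  // G -> C
    r[i] = c;
  }
  return r;
}

static void scan_exhaustive(const Masks &r, const Masks &t, int target,
                            int strand, int max_sub, int max_gap,
                            std::vector<Hit> &out) {
  const int m = (int)r.size(), L = (int)t.size();
  if (m == 0 || L < m - 1) return;
  int omax = L - m + (max_gap >= 1 ? 1 : 0);
  for (int o = 0; o <= omax; ++o) {
    int s, g;
    if (align_at(r, t, o, max_sub, max_gap, s, g))
      out.push_back(Hit{target, o, strand, s, g});
  }
}

// ---------- seeded matcher ----------

struct QIndex {
  // key: packed q-gram plus q in high bits; value: list of (target, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map;
};

static void index_insert(QIndex &ix, uint64_t key, int target, int pos) {
  ix.map[key].push_back(std::make_pair(target, pos));
}

// enumerate concrete packings of a reference window containing IUPAC codes;
// each expansion is inserted under qtag | packed-key
static void expand_window(const Masks &t, int pos, int q, uint64_t qtag,
                          uint64_t key, int i, QIndex &ix, int target,
                          int cap, int &count) {
  if (count > cap) return;
  if (i == q) { index_insert(ix, qtag | key, target, pos); count++; return; }
  int m = t[pos + i];
  if (m == 0) return;
  for (int b = 0; b < 4; ++b) {
    if (m & (1 << b)) {
      expand_window(t, pos, q, qtag, (key << 2) | (uint64_t)b, i + 1, ix,
                    target, cap, count);
      if (count > cap) return;
    }
  }
}

static bool pack_read_chunk(const Masks &r, int pos, int q, uint64_t &key) {
  key = 0;
  for (int i = 0; i < q; ++i) {
    int m = r[pos + i];
    int b;
    switch (m) { case 1: b = 0; break; case 2: b = 1; break;
                 case 4: b = 2; break; case 8: b = 3; break;
                 default: return false; }  // N: chunk cannot seed
    key = (key << 2) | (uint64_t)b;
  }
  return true;
}

static void seeded_scan(const Masks &r, const std::vector<Masks> &targets,
                        const std::vector<QIndex> &indices,
                        const std::vector<int> &qvals,
                        int strand, int max_sub, int max_gap,
                        std::vector<Hit> &out) {
  const int m = (int)r.size();
  int q = m / 4;  // 4 chunks; with <= max_sub+max_gap <= 3 errors one is clean
  // find index for this q
  int qi = -1;
  for (size_t i = 0; i < qvals.size(); ++i) if (qvals[i] == q) { qi = (int)i; }
  if (qi < 0) return;
  const QIndex &ix = indices[qi];
  uint64_t qtag = ((uint64_t)q) << 40;

  // candidate offsets per target, dedup via small set
  std::vector<std::pair<int,int>> cands;  // (target, offset)
  for (int c = 0; c < 4; ++c) {
    int rc = c * q;
    uint64_t key;
    if (!pack_read_chunk(r, rc, q, key)) continue;
    auto it = ix.map.find(qtag | key);
    if (it == ix.map.end()) continue;
    for (auto &tp : it->second) {
      int base = tp.second - rc;
      for (int d = -1; d <= 1; ++d) {
        if (d != 0 && max_gap < 1) continue;
        cands.push_back(std::make_pair(tp.first, base + d));
      }
    }
  }
  std::sort(cands.begin(), cands.end());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
  for (auto &cd : cands) {
    int s, g;
    const Masks &t = targets[cd.first];
    if (cd.second < 0 || cd.second >= (int)t.size()) continue;
    if (align_at(r, t, cd.second, max_sub, max_gap, s, g))
      out.push_back(Hit{cd.first, cd.second, strand, s, g});
  }
}

static DataFrame hits_to_df(const std::vector<std::vector<Hit>> &hits_per_read) {
  int n = 0;
  for (auto &h : hits_per_read) n += (int)h.size();
  IntegerVector read(n), target(n), offset(n), subs(n), gaps(n), dist(n);
  CharacterVector strand(n);
  int k = 0;
  for (size_t i = 0; i < hits_per_read.size(); ++i) {
    for (auto &h : hits_per_read[i]) {
      read[k] = (int)i + 1;
      target[k] = h.target + 1;
      offset[k] = h.offset;
      strand[k] = h.strand ? "-" : "+";
      subs[k] = h.subs;
      gaps[k] = h.gaps;
      dist[k] = h.subs + h.gaps;
      ++k;
    }
  }
  return DataFrame::create(_["read"] = read, _["target"] = target,
                           _["offset"] = offset, _["strand"] = strand,
                           _["subs"] = subs, _["gaps"] = gaps,
                           _["dist"] = dist,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".match_exhaustive_cpp")]]
DataFrame match_exhaustive_cpp(CharacterVector reads, CharacterVector refs,
                               int max_sub, int max_gap, bool both_strands) {
  std::vector<Masks> targets(refs.size());
  for (int i = 0; i < refs.size(); ++i)
    targets[i] = to_masks(as<std::string>(refs[i]), false);
  std::vector<std::vector<Hit>> res(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    Masks r = to_masks(as<std::string>(reads[i]), true);
    for (size_t t = 0; t < targets.size(); ++t) {
      scan_exhaustive(r, targets[t], (int)t, 0, max_sub, max_gap, res[i]);
      if (both_strands) {
        Masks rc = revcomp_masks(r);
        scan_exhaustive(rc, targets[t], (int)t, 1, max_sub, max_gap, res[i]);
      }
    }
  }
  return hits_to_df(res);
}

// [[Rcpp::export(name = ".match_seeded_cpp")]]
DataFrame match_seeded_cpp(CharacterVector reads, CharacterVector refs,
                           int max_sub, int max_gap, bool both_strands) {
  std::vector<Masks> targets(refs.size());
  for (int i = 0; i < refs.size(); ++i)
    targets[i] = to_masks(as<std::string>(refs[i]), false);

  // q values needed across reads
  std::vector<int> qvals;
  for (int i = 0; i < reads.size(); ++i) {
    int q = ((int)LENGTH(STRING_ELT(reads, i))) / 4;
    if (q >= 2 && std::find(qvals.begin(), qvals.end(), q) == qvals.end())
      qvals.push_back(q);
  }
  std::vector<QIndex> indices(qvals.size());
  const int cap = 4096;  // expansion cap per window (ambiguity is sparse)
  for (size_t qi = 0; qi < qvals.size(); ++qi) {
    int q = qvals[qi];
    uint64_t qtag = ((uint64_t)q) << 40;
    for (size_t t = 0; t < targets.size(); ++t) {
      const Masks &tm = targets[t];
      for (int p = 0; p + q <= (int)tm.size(); ++p) {
        int count = 0;
        // fast path: concrete window
        bool concrete = true;
        uint64_t key = 0;
        for (int i = 0; i < q; ++i) {
          int m = tm[p + i];
          int b;
          switch (m) { case 1: b = 0; break; case 2: b = 1; break;
                       case 4: b = 2; break; case 8: b = 3; break;
                       default: concrete = false; b = 0; }
          if (!concrete) break;
          key = (key << 2) | (uint64_t)b;
        }
        if (concrete) index_insert(indices[qi], qtag | key, (int)t, p);
        else expand_window(tm, p, q, qtag, 0, 0, indices[qi], (int)t, cap,
                           count);
      }
    }
  }

  std::vector<std::vector<Hit>> res(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    Masks r = to_masks(as<std::string>(reads[i]), true);
    seeded_scan(r, targets, indices, qvals, 0, max_sub, max_gap, res[i]);
    if (both_strands) {
      Masks rc = revcomp_masks(r);
      seeded_scan(rc, targets, indices, qvals, 1, max_sub, max_gap, res[i]);
    }
  }
  return hits_to_df(res);
}
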