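#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Seed-and-extend local alignment of reads against a small reference set:
// exact k-mer seeds hashed over all references, seed hits clustered by
// (reference, diagonal), each cluster extended by affine-gap Smith-Waterman
// (Gotoh) over a padded reference window. Both read strands are searched;
// read coordinates are reported on the original orientation. All intervals
// are 0-based half-open.

static inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct Aln {
  int refIdx, readS, readE, refS, refE, score;
  double identity;
  char strand;
};

// full Smith-Waterman (affine gaps) of read vs a reference window.
// The raw optimum may drag a low-identity tail across a ligation junction
// (net-positive chance matches), so the reported alignment is the
// maximal-scoring contiguous sub-segment of the optimal path whose
// identity meets minIdentity; returns false if no feasible segment
// reaches minScore.
static bool swAlign(const std::string& read, const std::string& ref,
                    int winS, int winE, int match, int mismatch,
                    int gapOpen, int gapExtend, int minScore,
                    double minIdentity, Aln& out) {
  const int n = read.size(), m = winE - winS;
  if (m <= 0) return false;
  // H, Eg (gap in read), Fg (gap in ref); traceback: 0 stop 1 diag 2 up 3 left
  std::vector<int> H((n + 1) * (m + 1), 0), Eg((n + 1) * (m + 1), -1000000),
      Fg((n + 1) * (m + 1), -1000000);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int ci = code(read[i - 1]);
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      size_t up = idx - (m + 1), left = idx - 1;
      Eg[idx] = std::max(Eg[up] - gapExtend, H[up] - gapOpen);
      Fg[idx] = std::max(Fg[left] - gapExtend, H[left] - gapOpen);
      int cj = code(ref[winS + j - 1]);
      int sub = (ci >= 0 && ci == cj) ? match : -mismatch;
      int diag = H[up - 1] + sub;
      int h = std::max(0, std::max(diag, std::max(Eg[idx], Fg[idx])));
      H[idx] = h;
      if (h == 0) tb[idx] = 0;
      else if (h == diag) tb[idx] = 1;
      else if (h == Eg[idx]) tb[idx] = 2;
      else tb[idx] = 3;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best < minScore) return false;
  // traceback, recording the path column by column (reverse order)
  struct Col { int readPos, refPos, score; bool isMatch, isGap; };
  std::vector<Col> path;
  {
    int i = bi, j = bj;
    bool inGap = false;
    while (i > 0 && j > 0) {
      size_t idx = (size_t)i * (m + 1) + j;
      unsigned char t = tb[idx];
      if (t == 0 || H[idx] == 0) break;
      Col c;
      if (t == 1) {
        int ci = code(read[i - 1]), cj = code(ref[winS + j - 1]);
        c.isMatch = (ci >= 0 && ci == cj);
        c.isGap = false;
        c.score = c.isMatch ? match : -mismatch;
        c.readPos = i - 1; c.refPos = winS + j - 1;
        --i; --j;
        inGap = false;
      } else {
        c.isMatch = false; c.isGap = true;
        c.score = inGap ? -gapExtend : -gapOpen;
        c.readPos = i - 1; c.refPos = winS + j - 1;
        if (t == 2) --i; else --j;
        inGap = true;
      }
      path.push_back(c);
    }
  }
  std::reverse(path.begin(), path.end());
  // gap-run costs were assigned in reverse; recompute forward
  for (size_t t = 0; t < path.size(); ++t)
    if (path[t].isGap)
      path[t].score = (t > 0 && path[t - 1].isGap) ? -gapExtend : -gapOpen;
  const int L = path.size();
  if (L == 0) return false;
  // best-scoring contiguous sub-segment with identity >= minIdentity,
  // boundaries on aligned (non-gap) columns
  int bestScore = -1, bS = -1, bE = -1, bMatch = 0, bLen = 0;
  for (int s = 0; s < L; ++s) {
    if (path[s].isGap) continue;
    int sc = 0, mt = 0;
    for (int e = s; e < L; ++e) {
      sc += path[e].score;
      if (path[e].isMatch) ++mt;
      if (path[e].isGap) continue;
      int len = e - s + 1;
      double ident = (double)mt / len;
      if (ident + 1e-12 >= minIdentity &&
          (sc > bestScore || (sc == bestScore && len > bLen))) {
        bestScore = sc; bS = s; bE = e; bMatch = mt; bLen = len;
      }
    }
  }
  if (bestScore < minScore) return false;
  out.readS = path[bS].readPos;
  out.readE = path[bE].readPos + 1;
  out.refS = path[bS].refPos;
  out.refE = path[bE].refPos + 1;
  out.score = bestScore;
  out.identity = (double)bMatch / bLen;
  return true;
}

// [[Rcpp::export(name = ".sw_align_batch_cpp")]]
DataFrame sw_align_batch_cpp(CharacterVector reads, CharacterVector refSeqs,
                             int k, int minScore, double minIdentity,
                             int match, int mismatch, int gapOpen,
                             int gapExtend) {
  const int nRef = refSeqs.size();
  std::vector<std::string> refs(nRef);
  for (int r = 0; r < nRef; ++r) refs[r] = as<std::string>(refSeqs[r]);

  // k-mer index over references
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  index.reserve(1 << 18);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int r = 0; r < nRef; ++r) {
    const std::string& s = refs[r];
    uint64_t key = 0;
    int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int c = code(s[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[key].push_back({r, (int)p - k + 1});
    }
  }

  std::vector<int> o_read, o_ref, o_readS, o_readE, o_refS, o_refE, o_score;
  std::vector<double> o_ident;
  std::vector<int> o_strand;

  struct Hit { int refIdx, refPos, readPos; };
  for (int q = 0; q < reads.size(); ++q) {
    std::string fwd = as<std::string>(reads[q]);
    std::vector<Aln> alns;
    for (int strand = 0; strand < 2; ++strand) {
      std::string rd = strand == 0 ? fwd : revcomp(fwd);
      const int n = rd.size();
      if (n < k) continue;
      std::vector<Hit> hits;
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < n; ++p) {
        int c = code(rd[p]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(key);
          if (it != index.end())
            for (auto& h : it->second)
              hits.push_back({h.first, h.second, p - k + 1});
        }
      }
      if (hits.empty()) continue;
      std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
        long da = (long)a.refPos - a.readPos, db = (long)b.refPos - b.readPos;
        if (a.refIdx != b.refIdx) return a.refIdx < b.refIdx;
        if (da != db) return da < db;
        return a.readPos < b.readPos;
      });
      // cluster by (ref, diagonal band); extend each cluster once
      size_t c0 = 0;
      for (size_t h = 1; h <= hits.size(); ++h) {
        bool brk = h == hits.size();
        if (!brk) {
          long d0 = (long)hits[h - 1].refPos - hits[h - 1].readPos;
          long d1 = (long)hits[h].refPos - hits[h].readPos;
          brk = hits[h].refIdx != hits[h - 1].refIdx ||
                std::llabs(d1 - d0) > 6 ||
                hits[h].readPos - hits[h - 1].readPos > 40;
        }
        if (brk) {
          const Hit& a = hits[c0];
          const Hit& b = hits[h - 1];
          int refLen = refs[a.refIdx].size();
          int winS = std::max(0, a.refPos - a.readPos - 12);
          int winE = std::min(refLen, b.refPos + k + (n - b.readPos) + 12);
          Aln al;
          if (swAlign(rd, refs[a.refIdx], winS, winE, match, mismatch,
                      gapOpen, gapExtend, minScore, minIdentity, al)) {
            al.refIdx = a.refIdx;
            al.strand = strand == 0 ? '+' : '-';
            if (strand == 1) {  // map intervals back to original read
              int s = al.readS, e = al.readE;
              al.readS = n - e; al.readE = n - s;
            }
            alns.push_back(al);
          }
          c0 = h;
        }
      }
    }
    // drop exact duplicates (same placement found via two clusters)
    std::sort(alns.begin(), alns.end(), [](const Aln& a, const Aln& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.refIdx != b.refIdx) return a.refIdx < b.refIdx;
      if (a.readS != b.readS) return a.readS < b.readS;
      return a.refS < b.refS;
    });
    alns.erase(std::unique(alns.begin(), alns.end(),
                           [](const Aln& a, const Aln& b) {
      return a.refIdx == b.refIdx && a.readS == b.readS && a.readE == b.readE &&
             a.refS == b.refS && a.refE == b.refE && a.strand == b.strand;
    }), alns.end());
    for (auto& al : alns) {
      o_read.push_back(q + 1);
      o_ref.push_back(al.refIdx + 1);
      o_readS.push_back(al.readS);
      o_readE.push_back(al.readE);
      o_refS.push_back(al.refS);
      o_refE.push_back(al.refE);
      o_score.push_back(al.score);
      o_ident.push_back(al.identity);
      o_strand.push_back(al.strand == '+' ? 1 : -1);
    }
  }
  return DataFrame::create(
      _["read_index"] = o_read, _["ref_index"] = o_ref,
      _["read_start"] = o_readS, _["read_end"] = o_readE,
      _["ref_start"] = o_refS, _["ref_end"] = o_refE,
      _["score"] = o_score, _["identity"] = o_ident,
      _["strand"] = o_strand);
}
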