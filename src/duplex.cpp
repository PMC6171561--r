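#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Intermolecular duplex minimum free energy by dynamic programming over
// pair states. Strand 1 runs 5'->3' (index i), strand 2 runs 5'->3'
// (index j); an antiparallel, non-crossing pairing is a chain of pairs
// strictly increasing in i and strictly decreasing in j. Transitions are
// stacks (adjacent pairs), bulges (one side unpaired) and internal loops
// (both sides), with loop sides bounded by maxLoop. Energy of a structure:
//   initiation + terminal AU/GU penalty at both helix ends
//              + sum of stack / loop terms between consecutive pairs.
// No intramolecular structure, dangles or coaxial stacking.

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

// pair type index into the 6x6 stack table: AU UA CG GC GU UG
static inline int pairType(int b1, int b2) {
  if (b1 == 0 && b2 == 3) return 0;
  if (b1 == 3 && b2 == 0) return 1;
  if (b1 == 1 && b2 == 2) return 2;
  if (b1 == 2 && b2 == 1) return 3;
  if (b1 == 2 && b2 == 3) return 4;
  if (b1 == 3 && b2 == 2) return 5;
  return -1;
}

static inline bool wobble(int pt) { return pt == 0 || pt == 1 || pt == 4 || pt == 5; }

// [[Rcpp::export(name = ".duplex_mfe_cpp")]]
List duplex_mfe_cpp(std::string s1, std::string s2, NumericMatrix stack,
                    NumericVector bulge, NumericVector internal,
                    double initiation, double terminalAU, int maxLoop) {
  const int n = s1.size(), m = s2.size();
  std::vector<int> b1(n), b2(m);
  for (int i = 0; i < n; ++i) {
    b1[i] = baseCode(s1[i]);
    if (b1[i] < 0) stop("invalid base '%c' in sequence 1", s1[i]);
  }
  for (int j = 0; j < m; ++j) {
    b2[j] = baseCode(s2[j]);
    if (b2[j] < 0) stop("invalid base '%c' in sequence 2", s2[j]);
  }
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> E((size_t)n * m, INF);
  std::vector<int> fromI((size_t)n * m, -1), fromJ((size_t)n * m, -1);
  std::vector<int> PT((size_t)n * m, -1);
  const int maxLoopLen = (int)bulge.size();

  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pt = pairType(b1[i], b2[j]);
      size_t idx = (size_t)i * m + j;
      PT[idx] = pt;
      if (pt < 0) continue;
      double best = initiation + (wobble(pt) ? terminalAU : 0.0);
      int bi = -1, bj = -1;
      int amax = std::min(maxLoop, i - 1);
      for (int a = 0; a <= amax; ++a) {
        int ip = i - 1 - a;
        int bmax = std::min(maxLoop, m - j - 2);
        for (int b = 0; b <= bmax; ++b) {
          int jp = j + 1 + b;
          size_t pidx = (size_t)ip * m + jp;
          if (!std::isfinite(E[pidx])) continue;
          double cost;
          if (a == 0 && b == 0) {
            cost = stack(PT[pidx], pt);
          } else {
            int len = a + b;
            if (len > maxLoopLen) continue;
            double pen = (a == 0 || b == 0) ? bulge[len - 1] : internal[len - 1];
            if (NumericVector::is_na(pen)) continue;
            cost = pen;
          }
          double cand = E[pidx] + cost;
          if (cand < best) { best = cand; bi = ip; bj = jp; }
        }
      }
      E[idx] = best;
      fromI[idx] = bi;
      fromJ[idx] = bj;
    }
  }

  double bestG = INF;
  int ei = -1, ej = -1;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      size_t idx = (size_t)i * m + j;
      if (!std::isfinite(E[idx])) continue;
      double g = E[idx] + (wobble(PT[idx]) ? terminalAU : 0.0);
      if (g < bestG) { bestG = g; ei = i; ej = j; }
    }

  if (!std::isfinite(bestG) || bestG > 0.0) {
    return List::create(_["deltaG"] = R_PosInf,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  std::vector<int> pi, pj;
  int ci = ei, cj = ej;
  while (ci >= 0) {
    pi.push_back(ci);
    pj.push_back(cj);
    size_t idx = (size_t)ci * m + cj;
    int ni = fromI[idx], nj = fromJ[idx];
    ci = ni; cj = nj;
  }
  int k = pi.size();
  IntegerMatrix pairs(k, 2);
  for (int t = 0; t < k; ++t) {      // reverse: ascending in pos1
    pairs(t, 0) = pi[k - 1 - t];
    pairs(t, 1) = pj[k - 1 - t];
  }
  return List::create(_["deltaG"] = bestG, _["pairs"] = pairs);
}
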