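// Nested-secondary-structure thermodynamics over a simplified
// nearest-neighbour model: McCaskill-style inside-outside partition
// function with base-pair probabilities, Zuker-style MFE with
// deterministic traceback, and Boltzmann stochastic traceback sampling.
//
// Conventions: 0-based indices internally, 1-based in returned pair
// matrices.  Partition arrays use long double so that no rescaling is
// required at the sequence lengths this package targets.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int pt[4][4];                 // pair-type index 0..5, -1 disallowed
  double stack[6][6];           // stack[outer][inner]
  std::vector<double> hp, bulge, interior;  // 1-based loop length -> energy
  double ml_a, ml_b, ml_c;      // multiloop offset / branch / unpaired
  int h;                        // minimum hairpin loop
  int maxloop;                  // cap on bulge/interior unpaired total
  double rt;
  // precomputed Boltzmann weights (filled by buildWeights)
  long double wstack[6][6];
  std::vector<long double> whp, wbulge, wint, wmlCpow;
  long double wmlA, wmlB, wmlC;
};

Model buildModel(const List& tab) {
  Model m;
  IntegerMatrix pt = tab["pt"];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) m.pt[a][b] = pt(a, b);
  NumericMatrix st = tab["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) m.stack[a][b] = st(a, b);
  m.hp = as<std::vector<double> >(tab["hairpin"]);
  m.bulge = as<std::vector<double> >(tab["bulge"]);
  m.interior = as<std::vector<double> >(tab["internal"]);
  NumericVector ml = tab["multiloop"];
  m.ml_a = ml[0]; m.ml_b = ml[1]; m.ml_c = ml[2];
  m.h = as<int>(tab["h"]);
  m.maxloop = as<int>(tab["maxloop"]);
  m.rt = as<double>(tab["rt"]);
  // Boltzmann-weight lookup tables: the inner DP loops only multiply
  size_t L = m.hp.size();
  m.whp.resize(L); m.wbulge.resize(L); m.wint.resize(L);
  for (size_t k = 0; k < L; ++k) {
    m.whp[k] = expl(-(long double)m.hp[k] / (long double)m.rt);
    m.wbulge[k] = expl(-(long double)m.bulge[k] / (long double)m.rt);
    m.wint[k] = expl(-(long double)m.interior[k] / (long double)m.rt);
  }
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      m.wstack[a][b] = expl(-(long double)m.stack[a][b] /
                            (long double)m.rt);
  m.wmlA = expl(-(long double)m.ml_a / (long double)m.rt);
  m.wmlB = expl(-(long double)m.ml_b / (long double)m.rt);
  m.wmlC = expl(-(long double)m.ml_c / (long double)m.rt);
  m.wmlCpow.resize(L + 2);
  m.wmlCpow[0] = 1.0L;
  for (size_t k = 1; k < L + 2; ++k)
    m.wmlCpow[k] = m.wmlCpow[k - 1] * m.wmlC;
  return m;
}

// Boltzmann weight of an interior-loop step (stack/bulge/interior)
inline long double eintW(const Model& m, const std::vector<int>& s,
                         int i, int j, int k, int l) {
  int l1 = k - i - 1, l2 = j - l - 1;
  if (l1 == 0 && l2 == 0)
    return m.wstack[m.pt[s[i]][s[j]]][m.pt[s[k]][s[l]]];
  if (l1 == 0 || l2 == 0) return m.wbulge[l1 + l2 - 1];
  return m.wint[l1 + l2 - 1];
}

// interior-loop energy: outer (i,j), inner (k,l), i < k < l < j
inline double eint(const Model& m, const std::vector<int>& s,
                   int i, int j, int k, int l) {
  int l1 = k - i - 1, l2 = j - l - 1;
  if (l1 == 0 && l2 == 0)
    return m.stack[m.pt[s[i]][s[j]]][m.pt[s[k]][s[l]]];
  if (l1 == 0 || l2 == 0) return m.bulge[l1 + l2 - 1];
  return m.interior[l1 + l2 - 1];
}

typedef long double ld;

struct PFArrays {
  int n;
  std::vector<ld> qb, qm, qm1;  // n*n
  std::vector<ld> q;            // prefix, size n+1, q[k] = first k bases
  std::vector<ld> qq;           // suffix, size n+2, qq[i] = bases i..n-1 (0-based), qq[n]=1
  ld& QB(int i, int j) { return qb[(size_t)i * n + j]; }
  ld& QM(int i, int j) { return qm[(size_t)i * n + j]; }
  ld& QM1(int i, int j) { return qm1[(size_t)i * n + j]; }
};

inline ld bw(const Model& m, double e) { return expl(-(ld)e / (ld)m.rt); }

void insideFill(const Model& m, const std::vector<int>& s, PFArrays& A) {
  int n = (int)s.size();
  A.n = n;
  A.qb.assign((size_t)n * n, 0.0L);
  A.qm.assign((size_t)n * n, 0.0L);
  A.qm1.assign((size_t)n * n, 0.0L);
  ld mlA = m.wmlA, mlB = m.wmlB, mlC = m.wmlC;
  for (int d = m.h + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // qb(i,j): substructures closed by pair (i,j)
      if (m.pt[s[i]][s[j]] >= 0) {
        ld v = m.whp[j - i - 1 - 1];  // hairpin, loop length j-i-1
        // interior loops (incl. stacks and bulges), unpaired total <= maxloop
        for (int k = i + 1; k <= j - m.h - 2 && k - i - 1 <= m.maxloop; ++k) {
          int minl = j - 1 - (m.maxloop - (k - i - 1));
          if (minl < k + m.h + 1) minl = k + m.h + 1;
          for (int l = j - 1; l >= minl; --l) {
            if (m.pt[s[k]][s[l]] < 0) continue;
            ld in = A.QB(k, l);
            if (in > 0.0L) v += eintW(m, s, i, j, k, l) * in;
          }
        }
        // multiloop: >= 2 branches inside the closing pair
        for (int k = i + 2; k <= j - m.h - 2; ++k) {
          ld left = A.QM(i + 1, k - 1);
          if (left > 0.0L) {
            ld right = A.QM1(k, j - 1);
            if (right > 0.0L) v += mlA * mlB * left * right;
          }
        }
        A.QB(i, j) = v;
      }
      // qm1(i,j): exactly one branch, starting at i, trailing unpaired
      {
        ld v = 0.0L;
        ld trail = 1.0L;
        for (int l = j; l >= i + m.h + 1; --l) {
          // trail = mlC^(j-l)
          if (l < j) trail *= mlC;
          ld b = A.QB(i, l);
          if (b > 0.0L) v += b * mlB * trail;
        }
        A.QM1(i, j) = v;
      }
      // qm(i,j): >= 1 branch; decompose on start k of last branch
      {
        ld v = 0.0L;
        ld lead = 1.0L;  // mlC^(k-i), all-unpaired prefix
        for (int k = i; k <= j - m.h - 1; ++k) {
          if (k > i) lead *= mlC;
          ld one = A.QM1(k, j);
          if (one > 0.0L) {
            v += lead * one;
            if (k > i) {
              ld pre = A.QM(i, k - 1);
              if (pre > 0.0L) v += pre * one;
            }
          }
        }
        A.QM(i, j) = v;
      }
    }
  }
  // exterior loop, prefix and suffix
  A.q.assign(n + 1, 0.0L);
  A.q[0] = 1.0L;
  for (int k = 1; k <= n; ++k) {
    ld v = A.q[k - 1];  // base k-1 (0-based) unpaired
    int j = k - 1;
    for (int i = 0; i <= j - m.h - 1; ++i) {
      ld b = A.QB(i, j);
      if (b > 0.0L) v += A.q[i] * b;
    }
    A.q[k] = v;
  }
  A.qq.assign(n + 2, 0.0L);
  A.qq[n] = 1.0L;
  for (int i = n - 1; i >= 0; --i) {
    ld v = A.qq[i + 1];
    for (int l = i + m.h + 1; l < n; ++l) {
      ld b = A.QB(i, l);
      if (b > 0.0L) v += b * A.qq[l + 1];
    }
    A.qq[i] = v;
  }
}

// outside pass: pair probabilities, push-style over decreasing spans
void pairProbabilities(const Model& m, const std::vector<int>& s,
                       PFArrays& A, std::vector<ld>& pr) {
  int n = A.n;
  pr.assign((size_t)n * n, 0.0L);
  ld Z = A.q[n];
  ld mlAB2 = m.wmlA * m.wmlB * m.wmlB;
  const ld negligible = 1e-16L;
  for (int d = n - 1; d >= m.h + 1; --d) {
    for (int k = 0; k + d < n; ++k) {
      int l = k + d;
      ld qbkl = A.QB(k, l);
      if (qbkl <= 0.0L) continue;
      size_t idx = (size_t)k * n + l;
      // exterior context
      pr[idx] += A.q[k] * qbkl * A.qq[l + 1] / Z;
      ld p = pr[idx];
      if (p <= negligible) continue;
      // push to interior-loop inner pairs
      for (int i = k + 1; i <= l - m.h - 2 && i - k - 1 <= m.maxloop; ++i) {
        int minj = l - 1 - (m.maxloop - (i - k - 1));
        if (minj < i + m.h + 1) minj = i + m.h + 1;
        for (int j = l - 1; j >= minj; --j) {
          ld qbij = A.QB(i, j);
          if (qbij <= 0.0L) continue;
          pr[(size_t)i * n + j] +=
            p * eintW(m, s, k, l, i, j) * qbij / qbkl;
        }
      }
      // push to multiloop branches inside (k,l)
      ld F = p / qbkl * mlAB2;
      for (int i = k + 1; i <= l - m.h - 2; ++i) {
        ld left = (i - 1 >= k + 1) ? A.QM(k + 1, i - 1) : 0.0L;
        ld uleft = m.wmlCpow[i - k - 1];
        for (int j = i + m.h + 1; j <= l - 1; ++j) {
          ld qbij = A.QB(i, j);
          if (qbij <= 0.0L) continue;
          ld right = (j + 1 <= l - 1) ? A.QM(j + 1, l - 1) : 0.0L;
          ld uright = m.wmlCpow[l - j - 1];
          ld ctx = left * (right + uright) + uleft * right;
          if (ctx > 0.0L) pr[(size_t)i * n + j] += F * qbij * ctx;
        }
      }
    }
  }
}

// ---------------- MFE ----------------

const double INF = 1e9;

struct MFEArrays {
  int n;
  std::vector<double> v, wm, wm1, w;
  double& V(int i, int j) { return v[(size_t)i * n + j]; }
  double& WM(int i, int j) { return wm[(size_t)i * n + j]; }
  double& WM1(int i, int j) { return wm1[(size_t)i * n + j]; }
};

void mfeFill(const Model& m, const std::vector<int>& s, MFEArrays& A) {
  int n = (int)s.size();
  A.n = n;
  A.v.assign((size_t)n * n, INF);
  A.wm.assign((size_t)n * n, INF);
  A.wm1.assign((size_t)n * n, INF);
  for (int d = m.h + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (m.pt[s[i]][s[j]] >= 0) {
        double best = m.hp[j - i - 1 - 1];
        for (int k = i + 1; k <= j - m.h - 2 && k - i - 1 <= m.maxloop; ++k) {
          int minl = j - 1 - (m.maxloop - (k - i - 1));
          if (minl < k + m.h + 1) minl = k + m.h + 1;
          for (int l = j - 1; l >= minl; --l) {
            if (m.pt[s[k]][s[l]] < 0 || A.V(k, l) >= INF) continue;
            double e = eint(m, s, i, j, k, l) + A.V(k, l);
            if (e < best) best = e;
          }
        }
        for (int k = i + 2; k <= j - m.h - 2; ++k) {
          double left = A.WM(i + 1, k - 1), right = A.WM1(k, j - 1);
          if (left < INF && right < INF) {
            double e = m.ml_a + m.ml_b + left + right;
            if (e < best) best = e;
          }
        }
        A.V(i, j) = best;
      }
      {
        double best = INF;
        for (int l = i + m.h + 1; l <= j; ++l) {
          if (A.V(i, l) < INF) {
            double e = A.V(i, l) + m.ml_b + m.ml_c * (j - l);
            if (e < best) best = e;
          }
        }
        A.WM1(i, j) = best;
      }
      {
        double best = INF;
        for (int k = i; k <= j - m.h - 1; ++k) {
          double one = A.WM1(k, j);
          if (one >= INF) continue;
          double lead = m.ml_c * (k - i);
          if (k > i && A.WM(i, k - 1) < lead) lead = A.WM(i, k - 1);
          if (lead + one < best) best = lead + one;
        }
        A.WM(i, j) = best;
      }
    }
  }
  A.w.assign(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) {
    double best = A.w[k - 1];
    int j = k - 1;
    for (int i = 0; i <= j - m.h - 1; ++i)
      if (A.V(i, j) < INF && A.w[i] + A.V(i, j) < best)
        best = A.w[i] + A.V(i, j);
    A.w[k] = best;
  }
}

const double TTOL = 1e-9;

void traceV(const Model& m, const std::vector<int>& s, MFEArrays& A,
            int i, int j, std::vector<std::pair<int,int> >& pairs);

void traceWM1(const Model& m, const std::vector<int>& s, MFEArrays& A,
              int i, int j, std::vector<std::pair<int,int> >& pairs) {
  for (int l = i + m.h + 1; l <= j; ++l) {
    if (A.V(i, l) < INF &&
        std::abs(A.V(i, l) + m.ml_b + m.ml_c * (j - l) - A.WM1(i, j)) < TTOL) {
      traceV(m, s, A, i, l, pairs);
      return;
    }
  }
  stop("MFE traceback failed (WM1)");
}

void traceWM(const Model& m, const std::vector<int>& s, MFEArrays& A,
             int i, int j, std::vector<std::pair<int,int> >& pairs) {
  for (int k = i; k <= j - m.h - 1; ++k) {
    double one = A.WM1(k, j);
    if (one >= INF) continue;
    if (std::abs(m.ml_c * (k - i) + one - A.WM(i, j)) < TTOL) {
      traceWM1(m, s, A, k, j, pairs);
      return;
    }
    if (k > i && A.WM(i, k - 1) < INF &&
        std::abs(A.WM(i, k - 1) + one - A.WM(i, j)) < TTOL) {
      traceWM(m, s, A, i, k - 1, pairs);
      traceWM1(m, s, A, k, j, pairs);
      return;
    }
  }
  stop("MFE traceback failed (WM)");
}

void traceV(const Model& m, const std::vector<int>& s, MFEArrays& A,
            int i, int j, std::vector<std::pair<int,int> >& pairs) {
  pairs.push_back(std::make_pair(i, j));
  double target = A.V(i, j);
  if (std::abs(m.hp[j - i - 1 - 1] - target) < TTOL) return;
  for (int k = i + 1; k <= j - m.h - 2 && k - i - 1 <= m.maxloop; ++k) {
    int minl = j - 1 - (m.maxloop - (k - i - 1));
    if (minl < k + m.h + 1) minl = k + m.h + 1;
    for (int l = j - 1; l >= minl; --l) {
      if (m.pt[s[k]][s[l]] < 0 || A.V(k, l) >= INF) continue;
      if (std::abs(eint(m, s, i, j, k, l) + A.V(k, l) - target) < TTOL) {
        traceV(m, s, A, k, l, pairs);
        return;
      }
    }
  }
  for (int k = i + 2; k <= j - m.h - 2; ++k) {
    double left = A.WM(i + 1, k - 1), right = A.WM1(k, j - 1);
    if (left < INF && right < INF &&
        std::abs(m.ml_a + m.ml_b + left + right - target) < TTOL) {
      traceWM(m, s, A, i + 1, k - 1, pairs);
      traceWM1(m, s, A, k, j - 1, pairs);
      return;
    }
  }
  stop("MFE traceback failed (V)");
}

// ---------------- stochastic traceback ----------------

void sampleQB(const Model& m, const std::vector<int>& s, PFArrays& A,
              int i, int j, std::vector<std::pair<int,int> >& pairs);

void sampleQM1(const Model& m, const std::vector<int>& s, PFArrays& A,
               int i, int j, std::vector<std::pair<int,int> >& pairs) {
  ld mlB = m.wmlB, mlC = m.wmlC;
  ld u = (ld)unif_rand() * A.QM1(i, j);
  ld acc = 0.0L;
  int lastl = -1;
  for (int l = i + m.h + 1; l <= j; ++l) {
    ld b = A.QB(i, l);
    if (b <= 0.0L) continue;
    lastl = l;
    acc += b * mlB * powl(mlC, (double)(j - l));
    if (acc >= u) break;
  }
  sampleQB(m, s, A, i, lastl, pairs);
}

void sampleQM(const Model& m, const std::vector<int>& s, PFArrays& A,
              int i, int j, std::vector<std::pair<int,int> >& pairs) {
  ld mlC = m.wmlC;
  ld u = (ld)unif_rand() * A.QM(i, j);
  ld acc = 0.0L;
  for (int k = i; k <= j - m.h - 1; ++k) {
    ld one = A.QM1(k, j);
    if (one <= 0.0L) continue;
    acc += powl(mlC, k - i) * one;
    if (acc >= u) { sampleQM1(m, s, A, k, j, pairs); return; }
    if (k > i) {
      ld pre = A.QM(i, k - 1);
      if (pre > 0.0L) {
        acc += pre * one;
        if (acc >= u) {
          sampleQM(m, s, A, i, k - 1, pairs);
          sampleQM1(m, s, A, k, j, pairs);
          return;
        }
      }
    }
  }
  // numerical slack: fall back to the last admissible single-branch case
  for (int k = j - m.h - 1; k >= i; --k)
    if (A.QM1(k, j) > 0.0L) { sampleQM1(m, s, A, k, j, pairs); return; }
  stop("stochastic traceback failed (QM)");
}

void sampleQB(const Model& m, const std::vector<int>& s, PFArrays& A,
              int i, int j, std::vector<std::pair<int,int> >& pairs) {
  pairs.push_back(std::make_pair(i, j));
  ld mlA = m.wmlA, mlB = m.wmlB;
  ld u = (ld)unif_rand() * A.QB(i, j);
  ld acc = m.whp[j - i - 1 - 1];
  if (acc >= u) return;  // hairpin
  for (int k = i + 1; k <= j - m.h - 2 && k - i - 1 <= m.maxloop; ++k) {
    int minl = j - 1 - (m.maxloop - (k - i - 1));
    if (minl < k + m.h + 1) minl = k + m.h + 1;
    for (int l = j - 1; l >= minl; --l) {
      ld in = A.QB(k, l);
      if (in <= 0.0L) continue;
      acc += eintW(m, s, i, j, k, l) * in;
      if (acc >= u) { sampleQB(m, s, A, k, l, pairs); return; }
    }
  }
  for (int k = i + 2; k <= j - m.h - 2; ++k) {
    ld left = A.QM(i + 1, k - 1);
    if (left <= 0.0L) continue;
    ld right = A.QM1(k, j - 1);
    if (right <= 0.0L) continue;
    acc += mlA * mlB * left * right;
    if (acc >= u) {
      sampleQM(m, s, A, i + 1, k - 1, pairs);
      sampleQM1(m, s, A, k, j - 1, pairs);
      return;
    }
  }
  return;  // numerical slack: treat as hairpin
}

void sampleQ(const Model& m, const std::vector<int>& s, PFArrays& A,
             int k, std::vector<std::pair<int,int> >& pairs) {
  while (k > 0) {
    ld u = (ld)unif_rand() * A.q[k];
    if (A.q[k - 1] >= u) { --k; continue; }
    ld acc = A.q[k - 1];
    int j = k - 1;
    bool done = false;
    for (int i = 0; i <= j - m.h - 1; ++i) {
      ld b = A.QB(i, j);
      if (b <= 0.0L) continue;
      acc += A.q[i] * b;
      if (acc >= u) {
        sampleQB(m, s, A, i, j, pairs);
        k = i;
        done = true;
        break;
      }
    }
    if (!done) --k;  // numerical slack
  }
}

IntegerMatrix pairsToMatrix(std::vector<std::pair<int,int> >& pairs) {
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (int r = 0; r < (int)pairs.size(); ++r) {
    out(r, 0) = pairs[r].first + 1;   // back to 1-based
    out(r, 1) = pairs[r].second + 1;
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cPartition")]]
List cPartition(IntegerVector codes, List tables) {
  Model m = buildModel(tables);
  std::vector<int> s = as<std::vector<int> >(codes);
  int n = (int)s.size();
  PFArrays A;
  insideFill(m, s, A);
  std::vector<ld> pr;
  pairProbabilities(m, s, A, pr);
  NumericMatrix P(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double p = (double)pr[(size_t)i * n + j];
      if (p < 0.0) p = 0.0;
      if (p > 1.0) p = 1.0;
      P(i, j) = p;
      P(j, i) = p;
    }
  return List::create(_["probs"] = P, _["logZ"] = (double)logl(A.q[n]));
}

// [[Rcpp::export(name = ".cMfe")]]
List cMfe(IntegerVector codes, List tables) {
  Model m = buildModel(tables);
  std::vector<int> s = as<std::vector<int> >(codes);
  int n = (int)s.size();
  MFEArrays A;
  mfeFill(m, s, A);
  // deterministic exterior traceback: unpaired first, then pairs by
  // ascending opening position
  std::vector<std::pair<int,int> > pairs;
  int k = n;
  while (k > 0) {
    if (std::abs(A.w[k - 1] - A.w[k]) < TTOL) { --k; continue; }
    int j = k - 1;
    bool found = false;
    for (int i = 0; i <= j - m.h - 1; ++i) {
      if (A.V(i, j) < INF &&
          std::abs(A.w[i] + A.V(i, j) - A.w[k]) < TTOL) {
        traceV(m, s, A, i, j, pairs);
        k = i;
        found = true;
        break;
      }
    }
    if (!found) stop("MFE traceback failed (W)");
  }
  return List::create(_["pairs"] = pairsToMatrix(pairs),
                      _["energy"] = A.w[n]);
}

// [[Rcpp::export(name = ".cSample")]]
List cSample(IntegerVector codes, List tables, int count) {
  Model m = buildModel(tables);
  std::vector<int> s = as<std::vector<int> >(codes);
  int n = (int)s.size();
  PFArrays A;
  insideFill(m, s, A);
  List out(count);
  for (int r = 0; r < count; ++r) {
    std::vector<std::pair<int,int> > pairs;
    sampleQ(m, s, A, n, pairs);
    out[r] = pairsToMatrix(pairs);
  }
  return out;
}
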