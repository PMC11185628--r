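// Generation-stepping engine: meiosis with Poisson recombination on
// source-labelled ancestry tracts, and weighted mate sampling under the
// random / stationary / increasing / broad / social mate-choice kernels.
//
// All randomness goes through R's RNG (unif_rand / rpois), so set.seed()
// at the R level fully determines a run.
//
// Population state is columnar. For individual i (0-based), haplotype h in
// {0,1} and chromosome c, the block index is (i*2 + h)*C + c. `nt[block]`
// tracts live in `ends` (their right endpoints, 0-based half-open, the last
// equal to the chromosome length); sources alternate starting from
// `src1[block]`, so maximal merging holds by construction.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// uniform integer on [0, n); one unif_rand() draw
static inline int unif_index(int n) {
  double u = unif_rand();
  int k = (int)(u * n);
  if (k >= n) k = n - 1;
  if (k < 0) k = 0;
  return k;
}

// sorted, deduplicated integer crossover positions on [0, len)
static void draw_crossovers_core(double len, double r, std::vector<double> &pos) {
  pos.clear();
  int n = (int)R::rpois(r * len);
  for (int i = 0; i < n; ++i) pos.push_back(std::floor(unif_rand() * len));
  std::sort(pos.begin(), pos.end());
  pos.erase(std::unique(pos.begin(), pos.end()), pos.end());
}

// read-only view of one haplotype-chromosome
struct HapView {
  const double *ends;
  int m;    // tract count
  int s0;   // source of first tract (1 or 2); sources alternate
};

static inline int tract_source(const HapView &h, int k) {
  return ((h.s0 - 1 + k) & 1) + 1;
}

// Append the piece [a, b) of haplotype `h` to a merged tract list
// (outEnds / outS0 / lastSrc); accumulates source-1 bp into src1bp.
static void copy_interval(const HapView &h, double a, double b,
                          std::vector<double> &outEnds, int &outS0,
                          int &lastSrc, double &src1bp) {
  if (b <= a) return;
  int k = (int)(std::upper_bound(h.ends, h.ends + h.m, a) - h.ends);
  double segStart = a;
  while (k < h.m) {
    double tEnd = h.ends[k];
    double segEnd = std::min(tEnd, b);
    int src = tract_source(h, k);
    if (outS0 == 0) {
      outS0 = src;
      outEnds.push_back(segEnd);
    } else if (src == lastSrc) {
      outEnds.back() = segEnd;
    } else {
      outEnds.push_back(segEnd);
    }
    lastSrc = src;
    if (src == 1) src1bp += segEnd - segStart;
    if (tEnd >= b) break;
    segStart = tEnd;
    ++k;
  }
}

// One gamete chromosome: independent assortment (fair coin for the starting
// haplotype), then alternate haplotypes at each crossover.
static void gamete_chrom(const HapView &h0, const HapView &h1, double len,
                         double r, std::vector<double> &outEnds, int &outS0,
                         double &src1bp, std::vector<double> &scratch) {
  draw_crossovers_core(len, r, scratch);
  int h = (unif_rand() < 0.5) ? 0 : 1;
  outEnds.clear();
  outS0 = 0;
  int lastSrc = 0;
  double a = 0.0;
  for (size_t i = 0; i <= scratch.size(); ++i) {
    double b = (i < scratch.size()) ? scratch[i] : len;
    copy_interval(h ? h1 : h0, a, b, outEnds, outS0, lastSrc, src1bp);
    a = b;
    h ^= 1;
  }
}

// [[Rcpp::export]]
NumericVector cpp_draw_crossovers(double len, double r) {
  std::vector<double> pos;
  draw_crossovers_core(len, r, pos);
  return wrap(pos);
}

// hap = list(ends = list of numeric per chromosome, src1 = integer vector)
// [[Rcpp::export]]
List cpp_meiosis(List hap1, List hap2, NumericVector chrom_lengths, double r) {
  int C = chrom_lengths.size();
  List e1 = hap1["ends"], e2 = hap2["ends"];
  IntegerVector s1 = hap1["src1"], s2 = hap2["src1"];
  List outEnds(C);
  IntegerVector outS0(C);
  double src1bp = 0.0;
  std::vector<double> buf, scratch;
  for (int c = 0; c < C; ++c) {
    NumericVector v1 = e1[c], v2 = e2[c];
    HapView h0 = {REAL(v1), (int)v1.size(), s1[c]};
    HapView h1 = {REAL(v2), (int)v2.size(), s2[c]};
    int s0 = 0;
    gamete_chrom(h0, h1, chrom_lengths[c], r, buf, s0, src1bp, scratch);
    outEnds[c] = NumericVector(buf.begin(), buf.end());
    outS0[c] = s0;
  }
  return List::create(_["ends"] = outEnds, _["src1"] = outS0,
                      _["source1_bp"] = src1bp);
}

// index of the j-th non-focal candidate under uniform weights;
// identical to the weighted scan with all weights equal to 1
static inline int mate_uniform(int p1, int N) {
  int j = unif_index(N - 1);
  return (j < p1) ? j : j + 1;
}

// weighted scan excluding the focal individual; one unif_rand() draw
static int mate_scan(int p1, int N, const double *w, double tot) {
  double u = unif_rand() * tot, cum = 0.0;
  int last = -1;
  for (int j = 0; j < N; ++j) {
    if (j == p1) continue;
    cum += w[j];
    last = j;
    if (u < cum) return j;
  }
  return last;
}

// [[Rcpp::export]]
List cpp_step_generation(List state, NumericVector chrom_lengths, double r,
                         int kind, double alpha, double var0,
                         double migration_rate) {
  NumericVector ends = state["ends"];
  IntegerVector nt = state["nt"];
  IntegerVector src1 = state["src1"];
  NumericVector x = state["x"];
  IntegerVector s = state["s"];
  int N = x.size();
  int C = chrom_lengths.size();
  double L = 0.0;
  for (int c = 0; c < C; ++c) L += chrom_lengths[c];

  // parental block offsets
  std::vector<long long> off((size_t)N * 2 * C + 1);
  off[0] = 0;
  for (long long i = 0; i < (long long)N * 2 * C; ++i) off[i + 1] = off[i] + nt[i];

  // kernel preparation (sigma_x^2(t) is computed once, before any mating)
  double var_t = 0.0;
  if (kind == 2) {
    double mu = 0.0, m2 = 0.0;
    for (int i = 0; i < N; ++i) mu += x[i];
    mu /= N;
    for (int i = 0; i < N; ++i) m2 += (x[i] - mu) * (x[i] - mu);
    var_t = m2 / N;
  }
  double lnA = (alpha > 0) ? std::log(alpha) : 0.0;
  double expRate = 0.0;  // exponent scale for stationary / increasing
  bool uniformKernel = false;
  if (kind == 1) {
    expRate = lnA;
    uniformKernel = (alpha == 1.0);
  } else if (kind == 2) {
    if (var_t > 0.0 && alpha > 1.0)
      expRate = lnA * var0 / var_t;
    else
      uniformKernel = true;  // degenerate population or alpha = 1
  }
  double inv2sig2 = 0.0;
  if (kind == 3) {
    if (alpha == 1.0)
      uniformKernel = true;
    else
      inv2sig2 = lnA;  // 1/(2*sigma^2) with sigma^2 = 1/(2*ln(alpha))
  }
  // social kernel
  double wSame = 1.0 - 1.0 / (alpha + 1.0);
  double wDiff = 1.0 / (alpha + 1.0);
  std::vector<int> gidx[2];
  std::vector<int> gpos(kind == 4 ? N : 0);
  if (kind == 4) {
    for (int i = 0; i < N; ++i) {
      int g = s[i] - 1;
      gpos[i] = (int)gidx[g].size();
      gidx[g].push_back(i);
    }
  }

  std::vector<double> w(N);

  // children (flat, with per-child offsets so migration can splice)
  std::vector<double> cEnds;
  cEnds.reserve(ends.size() + 1024);
  std::vector<int> cNt((size_t)N * 2 * C), cSrc1((size_t)N * 2 * C);
  std::vector<double> cx(N);
  std::vector<long long> childStart(N + 1);
  childStart[0] = 0;
  IntegerVector rp1(N), rp2(N);

  std::vector<double> buf, scratch;
  for (int k = 0; k < N; ++k) {
    int p1 = unif_index(N);
    int p2;
    if (kind == 0 || uniformKernel) {
      p2 = mate_uniform(p1, N);
    } else if (kind == 4) {
      int g = s[p1] - 1;
      int nSame = (int)gidx[g].size() - 1;
      int nOther = (int)gidx[1 - g].size();
      double tot = wSame * nSame + wDiff * nOther;
      double u = unif_rand() * tot;
      if (nSame > 0 && u < wSame * nSame) {
        int j = (int)(u / wSame);
        if (j >= nSame) j = nSame - 1;
        int pf = gpos[p1];
        p2 = gidx[g][(j < pf) ? j : j + 1];
      } else {
        double v = u - wSame * nSame;
        int j = (int)(v / wDiff);
        if (j >= nOther) j = nOther - 1;
        if (j < 0) j = 0;
        p2 = gidx[1 - g][j];
      }
    } else {
      double xi = x[p1], tot = 0.0;
      if (kind == 3) {
        for (int j = 0; j < N; ++j) {
          double d = xi - x[j];
          w[j] = std::exp(-d * d * inv2sig2);
          tot += w[j];
        }
      } else {
        for (int j = 0; j < N; ++j) {
          w[j] = std::exp(-expRate * std::fabs(xi - x[j]));
          tot += w[j];
        }
      }
      tot -= w[p1];
      p2 = mate_scan(p1, N, w.data(), tot);
    }
    rp1[k] = p1 + 1;
    rp2[k] = p2 + 1;

    double src1bp = 0.0;
    for (int h = 0; h < 2; ++h) {
      int par = (h == 0) ? p1 : p2;
      for (int c = 0; c < C; ++c) {
        long long b0 = ((long long)par * 2 + 0) * C + c;
        long long b1 = ((long long)par * 2 + 1) * C + c;
        HapView h0 = {REAL(ends) + off[b0], nt[b0], src1[b0]};
        HapView h1 = {REAL(ends) + off[b1], nt[b1], src1[b1]};
        int s0 = 0;
        gamete_chrom(h0, h1, chrom_lengths[c], r, buf, s0, src1bp, scratch);
        size_t blk = ((size_t)k * 2 + h) * C + c;
        cNt[blk] = (int)buf.size();
        cSrc1[blk] = s0;
        cEnds.insert(cEnds.end(), buf.begin(), buf.end());
      }
    }
    childStart[k + 1] = (long long)cEnds.size();
    cx[k] = src1bp / (2.0 * L);
  }

  IntegerVector cs(N);
  LogicalVector cmig(N);
  for (int k = 0; k < N; ++k) {
    cs[k] = s[rp1[k] - 1];
    cmig[k] = false;
  }

  // continuous migration: replace randomly chosen offspring with unadmixed
  // migrants, split round-half-even between the two sources
  int n_mig = (int)std::nearbyint(migration_rate * N);
  if (n_mig > 0) {
    std::vector<int> perm(N);
    for (int i = 0; i < N; ++i) perm[i] = i;
    for (int i = 0; i < n_mig; ++i) {
      int j = i + unif_index(N - i);
      std::swap(perm[i], perm[j]);
    }
    int n1 = (int)std::nearbyint(n_mig / 2.0);
    std::vector<int> migSrc(N, 0);
    for (int i = 0; i < n_mig; ++i) migSrc[perm[i]] = (i < n1) ? 1 : 2;

    std::vector<double> fEnds;
    fEnds.reserve(cEnds.size());
    for (int k = 0; k < N; ++k) {
      if (migSrc[k] == 0) {
        fEnds.insert(fEnds.end(), cEnds.begin() + childStart[k],
                     cEnds.begin() + childStart[k + 1]);
      } else {
        for (int h = 0; h < 2; ++h) {
          for (int c = 0; c < C; ++c) {
            size_t blk = ((size_t)k * 2 + h) * C + c;
            cNt[blk] = 1;
            cSrc1[blk] = migSrc[k];
            fEnds.push_back(chrom_lengths[c]);
          }
        }
        cx[k] = (migSrc[k] == 1) ? 1.0 : 0.0;
        cs[k] = migSrc[k];  // source 1 -> group A(1), source 2 -> group B(2)
        cmig[k] = true;
      }
    }
    cEnds.swap(fEnds);
  }

  return List::create(
      _["ends"] = NumericVector(cEnds.begin(), cEnds.end()),
      _["nt"] = IntegerVector(cNt.begin(), cNt.end()),
      _["src1"] = IntegerVector(cSrc1.begin(), cSrc1.end()),
      _["x"] = NumericVector(cx.begin(), cx.end()), _["s"] = cs,
      _["migrant"] = cmig, _["parent1"] = rp1, _["parent2"] = rp2,
      _["var_t"] = var_t);
}
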