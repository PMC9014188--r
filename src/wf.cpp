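#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Discrete Wright-Fisher reproduction for a diploid population with unlinked
// trait loci under Gaussian stabilizing selection on the summed phenotype.
//
// Layout: loci are stored column-major as vector<uint8_t> of per-individual
// copy counts (0/1/2) so that transmission and counting stream through memory.
// Loci with effect 0 are neutral markers: transmitted, never exposed to
// selection (they only enter fitness through nothing) and never folded into
// the substitution offset.

namespace {

// fair-coin source: R's generators emit 32 random bits per unif_rand() call
// (u = k / 2^32), so k can be recovered exactly and Mendelian segregation
// costs ~1/16 of an RNG draw per transmitted locus copy
struct BitCache {
  uint64_t bits = 0;
  int avail = 0;
  inline unsigned char next() {
    if (avail == 0) {
      bits = (uint64_t)(unif_rand() * 4294967296.0); // 2^32
      avail = 32;
    }
    unsigned char b = bits & 1u;
    bits >>= 1;
    --avail;
    return b;
  }
};

int sample_cum(const std::vector<double> &cum) {
  double u = unif_rand() * cum.back();
  return std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
}

} // namespace

// [[Rcpp::export]]
List wf_run_cpp(IntegerMatrix geno, NumericVector eff, IntegerVector locus_id,
                double offset, int ngen, double w, NumericVector opt,
                double env_sd, double U, NumericVector mix_w,
                NumericVector mix_sd, bool drop_fixed, int next_id,
                int record_every) {
  const int n = geno.nrow();
  int L = geno.ncol();
  if (U < 0) stop("mutation rate U must be non-negative");
  if (n < 2) stop("population size must be at least 2");
  const bool neutral = !R_finite(w);
  if (!neutral && w <= 0) stop("fitness peak width w must be positive or Inf");
  const double two_w2 = neutral ? 1.0 : 2.0 * w * w;
  const int first_new_id = next_id;

  std::vector<std::vector<unsigned char>> col(L);
  std::vector<double> a(L);
  std::vector<int> id(L);
  for (int l = 0; l < L; ++l) {
    col[l].resize(n);
    for (int i = 0; i < n; ++i) {
      int g = geno(i, l);
      if (g < 0 || g > 2) stop("genotypes must be copy counts in {0,1,2}");
      col[l][i] = (unsigned char)g;
    }
    a[l] = eff[l];
    id[l] = locus_id[l];
  }

  // mixture component cumulative weights for new mutation effects
  std::vector<double> mixcum(mix_w.size());
  double acc = 0.0;
  for (int k = 0; k < mix_w.size(); ++k) {
    acc += mix_w[k];
    mixcum[k] = acc;
  }

  std::vector<double> z(n), cum(n);
  std::vector<int> mother(n), father(n);
  std::vector<unsigned char> scratch(n);
  BitCache coin;

  int nrec = (record_every > 0) ? (ngen / record_every + 1) : 1;
  NumericMatrix rec(nrec, 5); // gen, mean_phen, V_a, V_A, n_seg
  int irec = 0;

  auto record = [&](int gen) {
    double mean = offset, va = 0.0;
    std::fill(z.begin(), z.end(), 0.0);
    int nseg = 0;
    for (int l = 0; l < L; ++l) {
      long tot = 0;
      for (int i = 0; i < n; ++i) tot += col[l][i];
      if (a[l] != 0.0) {
        double p = (double)tot / (2.0 * n);
        if (p > 0 && p < 1) ++nseg;
        va += 2.0 * p * (1.0 - p) * a[l] * a[l];
        mean += a[l] * (double)tot / n;
        for (int i = 0; i < n; ++i) z[i] += a[l] * col[l][i];
      }
    }
    double m = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) m += z[i];
    m /= n;
    for (int i = 0; i < n; ++i) ss += (z[i] - m) * (z[i] - m);
    rec(irec, 0) = gen;
    rec(irec, 1) = mean;
    rec(irec, 2) = va;
    rec(irec, 3) = ss / n;
    rec(irec, 4) = nseg;
    ++irec;
  };

  for (int gen = 0; gen < ngen; ++gen) {
    // additive genetic values
    std::fill(z.begin(), z.end(), offset);
    for (int l = 0; l < L; ++l) {
      double al = a[l];
      if (al == 0.0) continue;
      const std::vector<unsigned char> &c = col[l];
      for (int i = 0; i < n; ++i)
        if (c[i]) z[i] += al * c[i];
    }
    // fitness and parent sampling
    if (neutral) {
      for (int i = 0; i < n; ++i) {
        mother[i] = (int)(unif_rand() * n);
        father[i] = (int)(unif_rand() * n);
      }
    } else {
      double o = opt[(opt.size() == 1) ? 0 : gen];
      double run = 0.0;
      for (int i = 0; i < n; ++i) {
        double ph = z[i];
        if (env_sd > 0) ph += norm_rand() * env_sd;
        double d = ph - o;
        run += std::exp(-d * d / two_w2);
        cum[i] = run;
      }
      if (!(run > 0))
        stop("all fitnesses are zero: population too far from the optimum");
      for (int i = 0; i < n; ++i) {
        mother[i] = sample_cum(cum);
        father[i] = sample_cum(cum);
      }
    }
    // transmission, one locus at a time (free recombination); branchless
    // gamete: copy count 2 always transmits, 1 transmits a fair coin
    for (int l = 0; l < L; ++l) {
      std::vector<unsigned char> &c = col[l];
      for (int i = 0; i < n; ++i) {
        unsigned char gm = c[mother[i]], gf = c[father[i]];
        unsigned char ch = (unsigned char)((gm >> 1) + (gf >> 1));
        if (gm & 1u) ch += coin.next();
        if (gf & 1u) ch += coin.next();
        scratch[i] = ch;
      }
      c.swap(scratch);
    }
    // new mutations: Poisson(n*U) across the offspring generation
    if (U > 0) {
      int nmut = (int)R::rpois((double)n * U);
      for (int mcount = 0; mcount < nmut; ++mcount) {
        int carrier = (int)(unif_rand() * n);
        double u = unif_rand() * mixcum.back();
        int comp = std::lower_bound(mixcum.begin(), mixcum.end(), u) -
                   mixcum.begin();
        double anew = norm_rand() * mix_sd[comp];
        col.push_back(std::vector<unsigned char>(n, 0u));
        col.back()[carrier] = 1u;
        a.push_back(anew);
        id.push_back(next_id++);
        ++L;
      }
    }
    // fixation / loss bookkeeping
    int keep = 0;
    for (int l = 0; l < L; ++l) {
      long tot = 0;
      for (int i = 0; i < n; ++i) tot += col[l][i];
      bool lost = (tot == 0), fixed = (tot == 2L * n);
      bool remove = false;
      if (drop_fixed) {
        if (fixed) {
          offset += 2.0 * a[l];
          remove = true;
        } else if (lost) {
          remove = true;
        }
      } else {
        // keep ancestral columns aligned across populations; only discard
        // mutations born in this run that were immediately lost
        if (lost && id[l] >= first_new_id) remove = true;
      }
      if (!remove) {
        if (keep != l) {
          col[keep].swap(col[l]);
          a[keep] = a[l];
          id[keep] = id[l];
        }
        ++keep;
      }
    }
    col.resize(keep);
    a.resize(keep);
    id.resize(keep);
    L = keep;

    if (record_every > 0 && ((gen + 1) % record_every == 0) && irec < nrec)
      record(gen + 1);
  }
  if (record_every <= 0) record(ngen);

  IntegerMatrix out(n, L);
  NumericVector aout(L);
  IntegerVector idout(L);
  for (int l = 0; l < L; ++l) {
    aout[l] = a[l];
    idout[l] = id[l];
    for (int i = 0; i < n; ++i) out(i, l) = col[l][i];
  }
  return List::create(_["geno"] = out, _["eff"] = aout, _["id"] = idout,
                      _["offset"] = offset, _["next_id"] = next_id,
                      _["summary"] = rec(Range(0, std::max(irec - 1, 0)), _));
}
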