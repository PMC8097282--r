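#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Wright-Fisher forward simulation with exact ancestry tract recording.
//
// Chromosomes are stored as a sorted list of ancestry junction positions (in
// Morgans) plus the ancestry of the leftmost segment; ancestry alternates at
// each junction.  Selected-locus alleles are carried per chromosome and are
// inherited with the segment covering the locus, which allows the selected
// allele to segregate in the donor population (start frequency < 1).
// ---------------------------------------------------------------------------

struct Chrom {
  uint8_t anc0;                 // ancestry of leftmost segment (0 recipient, 1 donor)
  std::vector<double> br;      // junction positions, strictly increasing, in (0, L)
  std::vector<uint8_t> al;     // allele (0/1) at each tracked locus
};

static inline int anc_at(const Chrom &c, double x) {
  // ancestry immediately to the right of position x
  size_t n = std::upper_bound(c.br.begin(), c.br.end(), x) - c.br.begin();
  return c.anc0 ^ (n & 1u);
}

// build one gamete from the two chromosomes of a parent
static void make_gamete(const Chrom &c1, const Chrom &c2, double L,
                         const std::vector<double> &loci, Chrom &out) {
  int ncx = (int) R::rpois(L);
  std::vector<double> cx(ncx);
  for (int i = 0; i < ncx; ++i) cx[i] = unif_rand() * L;
  std::sort(cx.begin(), cx.end());

  bool first1 = unif_rand() < 0.5;
  out.br.clear();

  bool use1 = first1;
  const Chrom *src = use1 ? &c1 : &c2;
  int cur = anc_at(*src, 0.0);
  out.anc0 = (uint8_t) cur;

  double a = 0.0;
  for (int seg = 0; seg <= ncx; ++seg) {
    double b = (seg < ncx) ? cx[seg] : L;
    size_t i0 = std::upper_bound(src->br.begin(), src->br.end(), a) - src->br.begin();
    size_t i1 = std::lower_bound(src->br.begin(), src->br.end(), b) - src->br.begin();
    int sanc = (int) (src->anc0 ^ (i0 & 1u));
    for (size_t k = i0; k < i1; ++k) {
      sanc ^= 1;
      if (sanc != cur) { out.br.push_back(src->br[k]); cur = sanc; }
    }
    if (seg < ncx) {
      use1 = !use1;
      src = use1 ? &c1 : &c2;
      int nanc = anc_at(*src, b);
      if (nanc != cur) { out.br.push_back(b); cur = nanc; }
    }
    a = b;
  }

  size_t nl = loci.size();
  out.al.resize(nl);
  for (size_t l = 0; l < nl; ++l) {
    size_t seg = std::upper_bound(cx.begin(), cx.end(), loci[l]) - cx.begin();
    bool u1 = ((seg & 1u) == 0u) ? first1 : !first1;
    out.al[l] = u1 ? c1.al[l] : c2.al[l];
  }
}

// [[Rcpp::export]]
List cpp_wf_simulate(int N, double m, int t, double L,
                     NumericVector loci_pos, NumericVector loci_s,
                     NumericVector loci_h, NumericVector loci_start_freq,
                     int dmi_mode, int dmi_a, int dmi_b, double dmi_s,
                     double mig_rate, int mig_gens,
                     double stop_freq, int n_sample_ind) {
  const int nl = loci_pos.size();
  std::vector<double> loci(loci_pos.begin(), loci_pos.end());

  std::vector<Chrom> pop(2 * N), nxt(2 * N);
  for (int i = 0; i < 2 * N; ++i) {
    bool donor = unif_rand() < m;
    pop[i].anc0 = donor ? 1 : 0;
    pop[i].br.clear();
    pop[i].al.resize(nl);
    for (int l = 0; l < nl; ++l)
      pop[i].al[l] = (donor && unif_rand() < loci_start_freq[l]) ? 1 : 0;
  }

  NumericMatrix traj(t + 1, std::max(nl, 1));
  int stopped_at = t;
  bool stopped_early = false;

  std::vector<double> cumw(N);

  for (int g = 0; g <= t; ++g) {
    // record allele frequencies
    if (nl) {
      for (int l = 0; l < nl; ++l) {
        long cnt = 0;
        for (int i = 0; i < 2 * N; ++i) cnt += pop[i].al[l];
        traj(g, l) = (double) cnt / (2.0 * N);
      }
      if (stop_freq < 1.0 && traj(g, 0) >= stop_freq) {
        stopped_at = g; stopped_early = true;
        for (int gg = g + 1; gg <= t; ++gg)
          for (int l = 0; l < nl; ++l) traj(gg, l) = traj(g, l);
        break;
      }
    }
    if (g == t) break;

    // fitness of each diploid individual
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      const Chrom &ca = pop[2 * i], &cb = pop[2 * i + 1];
      double w = 1.0;
      for (int l = 0; l < nl; ++l) {
        if (loci_s[l] == 0.0) continue;
        int dos = ca.al[l] + cb.al[l];
        if (dos == 2) w *= 1.0 + 2.0 * loci_s[l];
        else if (dos == 1) w *= 1.0 + 2.0 * loci_s[l] * loci_h[l];
      }
      if (dmi_mode > 0) {
        bool a0 = ca.al[dmi_a] == 0 || cb.al[dmi_a] == 0;
        bool a1 = ca.al[dmi_a] == 1 || cb.al[dmi_a] == 1;
        bool b0 = ca.al[dmi_b] == 0 || cb.al[dmi_b] == 0;
        bool b1 = ca.al[dmi_b] == 1 || cb.al[dmi_b] == 1;
        bool hit = (dmi_mode == 1) ? ((a0 && b1) || (a1 && b0)) : (a0 && b1);
        if (hit) w *= 1.0 + dmi_s;
      }
      if (w < 0.0) w = 0.0;
      tot += w;
      cumw[i] = tot;
    }

    bool migration = mig_rate > 0.0 && g < mig_gens;
    for (int i = 0; i < N; ++i) {
      if (migration && unif_rand() < mig_rate) {
        // unadmixed donor migrant
        for (int c = 0; c < 2; ++c) {
          Chrom &ch = nxt[2 * i + c];
          ch.anc0 = 1; ch.br.clear(); ch.al.resize(nl);
          for (int l = 0; l < nl; ++l)
            ch.al[l] = (unif_rand() < loci_start_freq[l]) ? 1 : 0;
        }
        continue;
      }
      for (int c = 0; c < 2; ++c) {
        double u = unif_rand() * tot;
        int p = (int) (std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
        if (p >= N) p = N - 1;
        make_gamete(pop[2 * p], pop[2 * p + 1], L, loci, nxt[2 * i + c]);
      }
    }
    pop.swap(nxt);
  }

  // pack the sampled individuals (offspring are exchangeable; take the first)
  int ns = std::min(n_sample_ind, N);
  List chroms(2 * ns);
  for (int i = 0; i < 2 * ns; ++i) {
    const Chrom &c = pop[i];
    chroms[i] = List::create(
      _["anc0"] = (int) c.anc0,
      _["breaks"] = NumericVector(c.br.begin(), c.br.end()),
      _["alleles"] = IntegerVector(c.al.begin(), c.al.end()));
  }

  // genome-wide donor fraction in the full population (tract length weighted)
  double donor_len = 0.0;
  for (int i = 0; i < 2 * N; ++i) {
    const Chrom &c = pop[i];
    double a = 0.0; int anc = c.anc0;
    for (size_t k = 0; k <= c.br.size(); ++k) {
      double b = (k < c.br.size()) ? c.br[k] : L;
      if (anc == 1) donor_len += b - a;
      a = b; anc ^= 1;
    }
  }

  return List::create(
    _["chromosomes"] = chroms,
    _["trajectory"] = traj,
    _["stopped_at"] = stopped_at,
    _["stopped_early"] = stopped_early,
    _["donor_fraction"] = donor_len / (2.0 * N * L));
}

// ---------------------------------------------------------------------------
// Scaled forward algorithm for the ancestry-dosage chain.
//
// States are donor-chromosome counts 0..ploidy.  Per-interval single
// chromosome switch probabilities u (donor->recipient) and v
// (recipient->donor) are lifted to the dosage chain by assuming independent
// chromosomes: from dosage i, the next dosage is (i - X) + Y with
// X ~ Bin(i, u), Y ~ Bin(ploidy - i, v).
// ---------------------------------------------------------------------------

// binomial pmf over 0..n by the multiplicative recurrence (cheap for the
// modest n used here; avoids R::dbinom in the innermost loop)
static void binom_pmf(int n, double p, std::vector<double> &out) {
  if (p <= 0.0) {
    for (int x = 0; x <= n; ++x) out[x] = 0.0;
    out[0] = 1.0;
    return;
  }
  if (p >= 1.0) {
    for (int x = 0; x <= n; ++x) out[x] = 0.0;
    out[n] = 1.0;
    return;
  }
  double q = 1.0 - p, ratio = p / q;
  double val = std::pow(q, n);
  if (val > 0.0) {
    for (int x = 0; x <= n; ++x) {
      out[x] = val;
      val *= ratio * (double)(n - x) / (double)(x + 1);
    }
  } else {
    for (int x = 0; x <= n; ++x) out[x] = R::dbinom(x, n, p, 0);
  }
}

static void dosage_transition(int K, double u, double v,
                              std::vector<double> &T,
                              std::vector<double> &pX, std::vector<double> &pY) {
  // K = ploidy + 1 states; T is K*K row-major
  for (int i = 0; i < K; ++i) {
    int n1 = i, n0 = K - 1 - i;
    binom_pmf(n1, u, pX);
    binom_pmf(n0, v, pY);
    for (int j = 0; j < K; ++j) T[i * K + j] = 0.0;
    for (int x = 0; x <= n1; ++x) {
      int base = i - x;
      for (int y = 0; y <= n0; ++y) {
        int j = base + y;
        T[i * K + j] += pX[x] * pY[y];
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_dosage_transition(int ploidy, double u, double v) {
  int K = ploidy + 1;
  std::vector<double> T(K * K), pX(K), pY(K);
  dosage_transition(K, u, v, T, pX, pY);
  NumericMatrix out(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) out(i, j) = T[i * K + j];
  return out;
}

// [[Rcpp::export]]
double cpp_forward_loglik(List emissions, NumericVector u, NumericVector v,
                          int ploidy, NumericVector init) {
  const int K = ploidy + 1;
  const int S = emissions.size();
  std::vector<NumericMatrix> E(S);
  for (int s = 0; s < S; ++s) E[s] = as<NumericMatrix>(emissions[s]);
  const int n = E[0].nrow();
  if (u.size() != n - 1)
    stop("length(u) must equal nrow(emissions) - 1");

  std::vector<double> T(K * K), pX(K), pY(K);
  std::vector<double> alpha(S * K), anew(K);
  double loglik = 0.0;

  for (int s = 0; s < S; ++s) {
    double sc = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[s * K + k] = init[k] * E[s](0, k);
      sc += alpha[s * K + k];
    }
    if (sc <= 0.0) return R_NegInf;
    for (int k = 0; k < K; ++k) alpha[s * K + k] /= sc;
    loglik += std::log(sc);
  }

  for (int i = 0; i < n - 1; ++i) {
    dosage_transition(K, u[i], v[i], T, pX, pY);
    for (int s = 0; s < S; ++s) {
      double *a = &alpha[s * K];
      double sc = 0.0;
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) acc += a[k] * T[k * K + j];
        acc *= E[s](i + 1, j);
        anew[j] = acc;
        sc += acc;
      }
      if (sc <= 0.0) return R_NegInf;
      for (int j = 0; j < K; ++j) a[j] = anew[j] / sc;
      loglik += std::log(sc);
    }
  }
  return loglik;
}
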