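// Wright-Fisher generation cycle for the MHC host-pathogen models.
//
// The population is represented by genotype proportions over the current set
// of distinct alleles: deterministic Hardy-Weinberg proportions, viability
// selection through the genotype survival table, a multinomial draw of N
// surviving offspring over unordered genotype categories, then per-copy
// mutation (Binomial(2N, mu) events). This is exactly the cycle implemented
// by the exported R operations, compiled so that runs of 1e5-1e6 generations
// are routine.
//
// Condition is accumulated in log space (logc = log cmax + sum_k log mean
// efficiency); survival is evaluated as s = 1/(1 + exp(log K - logc)), which
// is algebraically c/(K + c) without ever forming the m-fold product. If
// every genotype's survival underflows to zero, selection falls back to
// relative weights exp(logc - max logc), which is the exact limit of the
// normalised selection step when all conditions are far below K.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <set>
#include <algorithm>
#include <type_traits>
using namespace Rcpp;

extern "C" void rmultinom(int n, double *prob, int K, int *rN);

static const int MODEL_NEUTRAL = 0, MODEL_GAUSSIAN = 1, MODEL_BITSTRING = 2;

static inline double surv(double logc, double logK) {
  double t = logK - logc;
  if (t == R_PosInf) return 0.0;
  double e = std::exp(t); // inf -> s = 0
  return 1.0 / (1.0 + e);
}

static int longest_run16(int agree) {
  int best = 0, run = 0;
  for (int i = 0; i < 16; ++i) {
    if ((agree >> i) & 1) {
      if (++run > best) best = run;
    } else run = 0;
  }
  return best;
}

struct Sim {
  int model, m, h, N;
  double v, a, sigma, logcmax, logK;
  const NumericMatrix *optima;   // m x h (gaussian)
  const IntegerMatrix *peptides; // m x npep (bitstring)

  std::vector<int> ids;
  std::vector<int> counts;
  std::vector<std::vector<double>> coords; // gaussian traits
  std::vector<int> codes;                  // bitstring codes
  std::vector<std::vector<double>> eff;    // per-allele efficiency over m pathogens
  std::vector<double> logc;                // n x n log-condition, row-major
  std::vector<std::vector<double>> bitcache;
  std::vector<char> bitcached;
  int next_id = 1;

  int n() const { return (int)ids.size(); }

  std::vector<double> efficiency_gaussian(const std::vector<double> &x) const {
    std::vector<double> e(m);
    for (int k = 0; k < m; ++k) {
      double d2 = 0.0;
      for (int j = 0; j < h; ++j) {
        double d = x[j] - (*optima)(k, j);
        d2 += d * d;
      }
      e[k] = std::exp(-0.5 * v * v * d2);
    }
    return e;
  }

  std::vector<double> efficiency_bitstring(int code) {
    if (bitcached[code]) return bitcache[code];
    int npep = peptides->ncol();
    std::vector<double> e(m);
    for (int k = 0; k < m; ++k) {
      // stable 1 - prod(1 - D): the efficiency never underflows to exact 0
      double log_miss = 0.0;
      for (int p = 0; p < npep; ++p) {
        int agree = (~(code ^ (*peptides)(k, p))) & 0xFFFF;
        int L = longest_run16(agree);
        double D = 1.0 / (1.0 + std::exp(a * (v - L)));
        log_miss += std::log1p(-D);
      }
      e[k] = -std::expm1(log_miss);
    }
    bitcache[code] = e;
    bitcached[code] = 1;
    return e;
  }

  double logc_pair(int i, int j) const {
    if (model == MODEL_NEUTRAL) return logcmax;
    double lc = logcmax;
    const std::vector<double> &ei = eff[i], &ej = eff[j];
    for (int k = 0; k < m; ++k) lc += std::log(0.5 * (ei[k] + ej[k]));
    return lc;
  }

  // append a fully constructed allele (eff already pushed) and extend logc
  void append_logc_row() {
    int nn = n(); // includes the new allele
    std::vector<double> nl((size_t)nn * nn);
    for (int i = 0; i < nn - 1; ++i)
      for (int j = 0; j < nn - 1; ++j)
        nl[(size_t)i * nn + j] = logc[(size_t)i * (nn - 1) + j];
    for (int i = 0; i < nn; ++i) {
      double lc = logc_pair(i, nn - 1);
      nl[(size_t)i * nn + (nn - 1)] = lc;
      nl[(size_t)(nn - 1) * nn + i] = lc;
    }
    logc.swap(nl);
  }

  void add_allele(const std::vector<double> &x, int code, int count) {
    ids.push_back(next_id++);
    counts.push_back(count);
    if (model == MODEL_GAUSSIAN) {
      coords.push_back(x);
      eff.push_back(efficiency_gaussian(x));
    } else if (model == MODEL_BITSTRING) {
      codes.push_back(code);
      eff.push_back(efficiency_bitstring(code));
    }
    append_logc_row();
  }

  void prune() {
    int nn = n();
    std::vector<int> keep;
    keep.reserve(nn);
    for (int i = 0; i < nn; ++i)
      if (counts[i] > 0) keep.push_back(i);
    if ((int)keep.size() == nn) return;
    int k = (int)keep.size();
    std::vector<double> nl((size_t)k * k);
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        nl[(size_t)i * k + j] = logc[(size_t)keep[i] * nn + keep[j]];
    logc.swap(nl);
    auto sub = [&keep](auto &vec) {
      typename std::remove_reference<decltype(vec)>::type out;
      out.reserve(keep.size());
      for (int i : keep) out.push_back(vec[i]);
      vec.swap(out);
    };
    sub(ids);
    sub(counts);
    if (model == MODEL_GAUSSIAN) { sub(coords); sub(eff); }
    if (model == MODEL_BITSTRING) { sub(codes); sub(eff); }
  }
};

// [[Rcpp::export]]
List cpp_wf_run(int model, int N, double mu, int generations, int thin,
                double cmax, double K,
                NumericMatrix optima, double v, double sigma,
                IntegerMatrix peptides, double a,
                NumericMatrix init_coords, IntegerVector init_codes,
                IntegerVector init_counts, bool record_alleles) {
  Sim S;
  S.model = model;
  S.N = N;
  S.v = v;
  S.a = a;
  S.sigma = sigma;
  S.logcmax = std::log(cmax);
  S.logK = std::log(K);
  S.optima = &optima;
  S.peptides = &peptides;
  S.m = (model == MODEL_GAUSSIAN) ? optima.nrow()
        : (model == MODEL_BITSTRING) ? peptides.nrow() : 0;
  S.h = (model == MODEL_GAUSSIAN) ? optima.ncol() : 0;
  if (model == MODEL_BITSTRING) {
    S.bitcache.resize(65536);
    S.bitcached.assign(65536, 0);
  }

  int n0 = init_counts.size();
  for (int i = 0; i < n0; ++i) {
    std::vector<double> x;
    int code = 0;
    if (model == MODEL_GAUSSIAN) {
      x.resize(S.h);
      for (int j = 0; j < S.h; ++j) x[j] = init_coords(i, j);
    } else if (model == MODEL_BITSTRING) {
      code = init_codes[i];
    }
    S.add_allele(x, code, init_counts[i]);
  }

  int n_snap_max = generations / thin + 3;
  NumericMatrix summary(n_snap_max, 5); // gen, n, ne, n_above, mean_survival
  List snaps(record_alleles ? n_snap_max : 0);
  int snap_i = 0;
  double twoN = 2.0 * N;
  double wbar_last = NA_REAL;

  auto record = [&](int gen) {
    int nn = S.n();
    double sumsq = 0.0;
    int above = 0;
    for (int i = 0; i < nn; ++i) {
      double q = S.counts[i] / twoN;
      sumsq += q * q;
      if (q >= 0.01) ++above;
    }
    summary(snap_i, 0) = gen;
    summary(snap_i, 1) = nn;
    summary(snap_i, 2) = 1.0 / sumsq;
    summary(snap_i, 3) = above;
    summary(snap_i, 4) = wbar_last;
    if (record_alleles) {
      RObject repr = R_NilValue;
      if (model == MODEL_GAUSSIAN) {
        NumericMatrix cm(nn, S.h);
        for (int i = 0; i < nn; ++i)
          for (int j = 0; j < S.h; ++j) cm(i, j) = S.coords[i][j];
        repr = cm;
      } else if (model == MODEL_BITSTRING) {
        repr = IntegerVector(S.codes.begin(), S.codes.end());
      }
      snaps[snap_i] = List::create(
          _["generation"] = gen,
          _["id"] = IntegerVector(S.ids.begin(), S.ids.end()),
          _["count"] = IntegerVector(S.counts.begin(), S.counts.end()),
          _["repr"] = repr);
    }
    ++snap_i;
  };

  record(0);

  std::vector<double> prob;
  std::vector<int> cell_i, cell_j, draw;

  for (int gen = 1; gen <= generations; ++gen) {
    if (gen % 4096 == 0) Rcpp::checkUserInterrupt();
    int nn = S.n();
    int ncell = nn * (nn + 1) / 2;
    prob.assign(ncell, 0.0);
    cell_i.resize(ncell);
    cell_j.resize(ncell);
    draw.assign(ncell, 0);

    // Hardy-Weinberg + viability selection over unordered genotype cells
    double wbar = 0.0, max_lc = R_NegInf;
    int c = 0;
    for (int i = 0; i < nn; ++i) {
      double qi = S.counts[i] / twoN;
      for (int j = i; j < nn; ++j, ++c) {
        cell_i[c] = i;
        cell_j[c] = j;
        double qq = (i == j ? qi * qi : 2.0 * qi * (S.counts[j] / twoN));
        double lc = S.logc[(size_t)i * nn + j];
        double w = qq * surv(lc, S.logK);
        prob[c] = w;
        wbar += w;
        if (qq > 0.0 && lc > max_lc) max_lc = lc;
      }
    }
    if (wbar <= 0.0) {
      // all survivals underflow: use relative weights c_ij / max c_ij
      if (max_lc == R_NegInf)
        stop("population extinct at generation %d: every genotype has zero survival", gen);
      c = 0;
      for (int i = 0; i < nn; ++i) {
        double qi = S.counts[i] / twoN;
        for (int j = i; j < nn; ++j, ++c) {
          double qq = (i == j ? qi * qi : 2.0 * qi * (S.counts[j] / twoN));
          prob[c] = qq * std::exp(S.logc[(size_t)i * nn + j] - max_lc);
        }
      }
      double tot = 0.0;
      for (double p : prob) tot += p;
      if (tot <= 0.0)
        stop("population extinct at generation %d: every genotype has zero survival", gen);
      wbar = tot; // only used for normalisation below; mean survival ~ 0
      wbar_last = 0.0;
    } else {
      wbar_last = wbar;
    }
    for (int k = 0; k < ncell; ++k) prob[k] /= wbar;

    // multinomial draw of N surviving offspring
    rmultinom(N, prob.data(), ncell, draw.data());

    std::fill(S.counts.begin(), S.counts.end(), 0);
    for (int k = 0; k < ncell; ++k) {
      if (draw[k] == 0) continue;
      S.counts[cell_i[k]] += draw[k];
      S.counts[cell_j[k]] += draw[k];
    }
    S.prune();

    // per-copy mutation: Binomial(2N, mu) events over distinct copies
    int tot = (int)twoN;
    int nmut = (int)R::rbinom(twoN, mu);
    std::vector<int> copies;
    if (nmut >= tot) {
      copies.resize(tot);
      for (int i = 0; i < tot; ++i) copies[i] = i;
    } else if (nmut > tot / 4) {
      std::vector<int> idx(tot);
      for (int i = 0; i < tot; ++i) idx[i] = i;
      for (int i = 0; i < nmut; ++i) { // partial Fisher-Yates
        int j = i + (int)(unif_rand() * (tot - i));
        if (j >= tot) j = tot - 1;
        std::swap(idx[i], idx[j]);
        copies.push_back(idx[i]);
      }
    } else if (nmut > 0) {
      std::set<int> seen;
      while ((int)copies.size() < nmut) {
        int c2 = (int)(unif_rand() * tot);
        if (c2 >= tot) c2 = tot - 1;
        if (seen.insert(c2).second) copies.push_back(c2);
      }
    }
    // donors resolved against the pre-mutation copy pool
    int n0 = S.n();
    std::vector<int> cum0(n0);
    int acc = 0;
    for (int i = 0; i < n0; ++i) { acc += S.counts[i]; cum0[i] = acc; }
    for (int copy : copies) {
      int donor = (int)(std::upper_bound(cum0.begin(), cum0.end(), copy) -
                        cum0.begin());
      S.counts[donor] -= 1;
      if (S.model == MODEL_GAUSSIAN) {
        std::vector<double> x = S.coords[donor];
        for (int j = 0; j < S.h; ++j) x[j] += S.sigma * norm_rand();
        S.add_allele(x, 0, 1);
      } else if (S.model == MODEL_BITSTRING) {
        int bit = (int)(unif_rand() * 16.0);
        if (bit >= 16) bit = 15;
        int code = S.codes[donor] ^ (1 << bit);
        int hit = -1;
        for (int i = 0; i < S.n(); ++i)
          if (S.codes[i] == code) { hit = i; break; }
        if (hit >= 0) S.counts[hit] += 1;
        else S.add_allele(std::vector<double>(), code, 1);
      } else {
        S.add_allele(std::vector<double>(), 0, 1);
      }
    }
    S.prune();

    if (gen % thin == 0 || gen == generations) record(gen);
  }

  // final state
  int nn = S.n();
  RObject repr = R_NilValue;
  if (model == MODEL_GAUSSIAN) {
    NumericMatrix cm(nn, S.h);
    for (int i = 0; i < nn; ++i)
      for (int j = 0; j < S.h; ++j) cm(i, j) = S.coords[i][j];
    repr = cm;
  } else if (model == MODEL_BITSTRING) {
    repr = IntegerVector(S.codes.begin(), S.codes.end());
  }
  NumericMatrix effm(nn, std::max(S.m, 0));
  if (model != MODEL_NEUTRAL)
    for (int i = 0; i < nn; ++i)
      for (int k = 0; k < S.m; ++k) effm(i, k) = S.eff[i][k];

  RObject snaps_out = R_NilValue;
  if (record_alleles) {
    List s2(snap_i);
    for (int i = 0; i < snap_i; ++i) s2[i] = snaps[i];
    snaps_out = s2;
  }

  return List::create(
      _["summary"] = summary(Range(0, snap_i - 1), _),
      _["snapshots"] = snaps_out,
      _["final_id"] = IntegerVector(S.ids.begin(), S.ids.end()),
      _["final_count"] = IntegerVector(S.counts.begin(), S.counts.end()),
      _["final_repr"] = repr,
      _["final_eff"] = effm,
      _["n_generations"] = generations);
}
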