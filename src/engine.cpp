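// Simulation engine: organism development (cell-lineage expansion with
// mitochondrial mutation, duplication and hypergeometric partition),
// post-developmental ageing, and the per-generation population loop
// (selection, gametogenesis, fertilisation, nuclear transmission).
//
// All randomness is drawn from R's global RNG (RNGScope), so whole runs are
// reproducible with set.seed() from R.
//
// Conventions:
//  - a cell is (m, tot): mutant count and total mitochondria;
//  - cells are kept in ancestry order, so the descendants of precursor cell
//    i at division T occupy a contiguous block and tissue = block index;
//  - nuclear alleles are coded 1 (resident) / 2 (invader); the W slot is 0
//    for males;
//  - post-developmental ageing collapses the remaining time units into one
//    binomial draw per cell with per-copy probability 1 - (1 - muB)^k,
//    which is exactly equivalent to k sequential rounds because copies
//    mutate independently and never back-mutate.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int draw_binom(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return static_cast<int>(R::rbinom(static_cast<double>(n), p));
}

// white drawn in a sample of k from m white + n black, without replacement
static inline int draw_hyper(int m, int n, int k) {
  if (m == 0 || k == 0) return 0;
  if (n == 0) return k;
  return static_cast<int>(R::rhyper(static_cast<double>(m),
                                    static_cast<double>(n),
                                    static_cast<double>(k)));
}

static inline int draw_index(int n) {  // uniform on 0..n-1
  int i = static_cast<int>(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

// One cell division following divide_cell() semantics.  Returns daughter
// mutant counts through d1/d2 and the new total through tot.
static inline void divide_one(int m, int &tot, int M, double muS, double muB,
                              int &d1, int &d2) {
  m += draw_binom(tot - m, muB);
  if (tot > M) {
    int half = tot / 2;
    d1 = draw_hyper(m, tot - m, half);
    d2 = m - d1;
    tot = half;
  } else {
    m += draw_binom(tot - m, muS);
    d1 = draw_hyper(2 * m, 2 * (tot - m), M);
    d2 = 2 * m - d1;
    // tot stays M
  }
}

struct Adult {
  std::vector<int> cells;  // 2^L somatic mutant counts, ancestry order
  int cell_total;
  std::vector<int> germ;   // 2^A germ-cell mutant counts
  int germ_total;
  double fitness;
};

// Develop one organism from a zygote and age it to `age_to` time units.
// Germ cells are sequestered after division NG by copying a random cell,
// proliferate for A further divisions (one per time unit), and accumulate
// background mutation once per time unit from NG+1 onwards.
static void develop_age_one(int zm, int zt, int M, int L, int NG, int A,
                            int age_to, double muS, double muB, Adult &out) {
  std::vector<int> cells(1, zm), next;
  int tot = zt;
  out.germ.clear();
  out.germ_total = 0;

  for (int t = 1; t <= L; ++t) {
    next.resize(cells.size() * 2);
    int newtot = tot;
    for (size_t i = 0; i < cells.size(); ++i) {
      int ct = tot;
      divide_one(cells[i], ct, M, muS, muB, next[2 * i], next[2 * i + 1]);
      newtot = ct;
    }
    cells.swap(next);
    tot = newtot;

    if (t == NG) {
      out.germ.assign(1, cells[draw_index(static_cast<int>(cells.size()))]);
      out.germ_total = tot;
    } else if (t > NG && !out.germ.empty()) {
      if (t <= NG + A) {  // proliferative germline division
        std::vector<int> g2(out.germ.size() * 2);
        int gt = out.germ_total;
        for (size_t i = 0; i < out.germ.size(); ++i) {
          int ct = out.germ_total;
          divide_one(out.germ[i], ct, M, muS, muB, g2[2 * i], g2[2 * i + 1]);
          gt = ct;
        }
        out.germ.swap(g2);
        out.germ_total = gt;
      } else {  // quiescent germ cells: background damage only
        for (size_t i = 0; i < out.germ.size(); ++i)
          out.germ[i] += draw_binom(out.germ_total - out.germ[i], muB);
      }
    }
  }

  // post-developmental ageing, collapsed into one draw per cell
  int k = age_to - L;
  if (k > 0 && muB > 0.0) {
    double peff = 1.0 - std::pow(1.0 - muB, k);
    for (size_t i = 0; i < cells.size(); ++i)
      cells[i] += draw_binom(tot - cells[i], peff);
    for (size_t i = 0; i < out.germ.size(); ++i)
      out.germ[i] += draw_binom(out.germ_total - out.germ[i], peff);
  }
  out.cells.swap(cells);
  out.cell_total = tot;
}

// Adult fitness: tissues are contiguous blocks of 2^(L-T) cells; tissue
// fitness is the mean of 1 - s (m/tot)^xi over its cells; adult fitness
// interpolates between the mean (eps = 0) and the minimum (eps = 1,
// worst-tissue epistasis, the default) of the tissue fitnesses.
static double adult_fitness_cpp(const std::vector<int> &cells, int tot,
                                int T, double s, double xi, double eps) {
  int n = static_cast<int>(cells.size());
  int ntis = 1 << T;
  int per = n / ntis;
  double minf = 2.0, sumf = 0.0;
  for (int t = 0; t < ntis; ++t) {
    double acc = 0.0;
    for (int i = t * per; i < (t + 1) * per; ++i)
      acc += 1.0 - s * std::pow(static_cast<double>(cells[i]) / tot, xi);
    double f = acc / per;
    sumf += f;
    if (f < minf) minf = f;
  }
  return (1.0 - eps) * (sumf / ntis) + eps * minf;
}

// [[Rcpp::export]]
List cpp_develop(int zm, int zt, int M, int L, int NG, int A, int age_to,
                 double muS, double muB) {
  Adult a;
  develop_age_one(zm, zt, M, L, NG, A, age_to, muS, muB, a);
  return List::create(_["cells"] = IntegerVector(a.cells.begin(),
                                                 a.cells.end()),
                      _["cell_total"] = a.cell_total,
                      _["germ"] = IntegerVector(a.germ.begin(), a.germ.end()),
                      _["germ_total"] = a.germ_total);
}

// [[Rcpp::export]]
double cpp_adult_fitness(IntegerVector cells, int tot, int T, double s,
                         double xi, double eps) {
  std::vector<int> c(cells.begin(), cells.end());
  return adult_fitness_cpp(c, tot, T, s, xi, eps);
}

// weighted sampling with replacement; returns `draws` indices into idx
static void sample_weighted(const std::vector<int> &idx,
                            const std::vector<double> &w, int draws,
                            std::vector<int> &out, bool &fallback) {
  double total = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) total += w[idx[i]];
  out.resize(draws);
  if (total <= 0.0) {  // all fitnesses zero: fall back to uniform
    fallback = true;
    for (int d = 0; d < draws; ++d)
      out[d] = idx[draw_index(static_cast<int>(idx.size()))];
    return;
  }
  std::vector<double> cum(idx.size());
  double acc = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) {
    acc += w[idx[i]];
    cum[i] = acc;
  }
  for (int d = 0; d < draws; ++d) {
    double u = unif_rand() * total;
    int lo = 0, hi = static_cast<int>(idx.size()) - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    out[d] = idx[lo];
  }
}

static inline int log2_exact(int x) {
  int j = 0;
  while (x > 1) { x >>= 1; ++j; }
  return j;
}

// Oogamy amplification (Q - j rounds of copy-error mutation + duplication),
// then meiosis: one duplication without mutation and two hypergeometric
// halvings, yielding an egg of 2^Q M / 2 mitochondria.
static void make_egg(int gm, int gt, int M, int Q, double muS,
                     int &egg_m, int &egg_tot) {
  int j = log2_exact(gt / M);
  int rounds = Q - j;
  if (rounds < 0)
    stop("germ cell already exceeds the oogamy target 2^Q M");
  for (int r = 0; r < rounds; ++r) {
    gm += draw_binom(gt - gm, muS);
    gm *= 2; gt *= 2;
  }
  // meiosis: duplicate, then two successive halvings without replacement
  int m2 = 2 * gm, t2 = 2 * gt;
  int h1 = draw_hyper(m2, t2 - m2, t2 / 2);
  int t1 = t2 / 2;
  egg_m = draw_hyper(h1, t1 - h1, t1 / 2);
  egg_tot = t1 / 2;  // = 2^Q M / 2
}

// One full discrete generation: develop and age every individual, apply
// fitness-weighted selection within each sex, then produce exactly N new
// zygotes (N/2 female, N/2 male, quota filled by rejection on offspring
// sex).  Mitochondria are inherited strictly maternally; the zygote content
// is resampled with replacement from the egg to 2^Q M copies.
//
// tabNG/tabA: phenotype of autosomal alleles 1 and 2 (germline timing and
// proliferation); tabQ: oogamy level of W alleles 1 and 2; `dominant` names
// the allele expressed in autosomal heterozygotes.
// [[Rcpp::export]]
List cpp_next_generation(IntegerVector sex, IntegerVector a1,
                         IntegerVector a2, IntegerVector w,
                         IntegerVector zm, IntegerVector zt,
                         int M, int L, int T, int S,
                         double muS, double muB,
                         double s, double xi, double eps,
                         IntegerVector tabNG, IntegerVector tabA,
                         IntegerVector tabQ, int dominant) {
  int N = sex.size();
  if (N % 2 != 0) stop("population size must be even");

  std::vector<Adult> adults(N);
  std::vector<double> fit(N);
  double fit_sum = 0.0, fit_min = 2.0, load_sum = 0.0;

  for (int i = 0; i < N; ++i) {
    int al1 = a1[i], al2 = a2[i];
    int expr = (al1 == al2) ? al1 : dominant;
    int NG = tabNG[expr - 1], A = tabA[expr - 1];
    develop_age_one(zm[i], zt[i], M, L, NG, A, S, muS, muB, adults[i]);
    fit[i] = adult_fitness_cpp(adults[i].cells, adults[i].cell_total, T, s,
                               xi, eps);
    fit_sum += fit[i];
    if (fit[i] < fit_min) fit_min = fit[i];
    load_sum += static_cast<double>(zm[i]) / zt[i];
  }

  std::vector<int> females, males;
  for (int i = 0; i < N; ++i) (sex[i] == 1 ? females : males).push_back(i);
  if (females.empty() || males.empty())
    stop("population must contain both sexes");

  bool fallback = false;
  std::vector<int> mothers, fathers;
  sample_weighted(females, fit, N / 2, mothers, fallback);
  sample_weighted(males, fit, N / 2, fathers, fallback);

  IntegerVector csex(N), ca1(N), ca2(N), cw(N), czm(N), czt(N);
  int nf = 0, nm = 0, placed = 0;
  while (placed < N) {
    int mi = mothers[draw_index(N / 2)];
    int fi = fathers[draw_index(N / 2)];
    // mother transmits W or Z equiprobably; father always transmits Z
    bool child_female = unif_rand() < 0.5;
    if (child_female ? nf >= N / 2 : nm >= N / 2) continue;

    int k = placed++;
    csex[k] = child_female ? 1 : 0;
    if (child_female) ++nf; else ++nm;
    ca1[k] = (unif_rand() < 0.5) ? a1[mi] : a2[mi];
    ca2[k] = (unif_rand() < 0.5) ? a1[fi] : a2[fi];
    cw[k] = child_female ? w[mi] : 0;

    // maternal mitochondria: random atresia among the mother's germ cells,
    // oogamy amplification at the mother's Q, fresh meiosis per offspring
    const Adult &mom = adults[mi];
    int g = draw_index(static_cast<int>(mom.germ.size()));
    int Q = tabQ[w[mi] - 1];
    int egg_m, egg_tot;
    make_egg(mom.germ[g], mom.germ_total, M, Q, muS, egg_m, egg_tot);
    int zt_child = 2 * egg_tot;  // 2^Q M
    czm[k] = draw_binom(zt_child,
                        static_cast<double>(egg_m) / egg_tot);
    czt[k] = zt_child;
  }

  return List::create(
    _["sex"] = csex, _["a1"] = ca1, _["a2"] = ca2, _["w"] = cw,
    _["zm"] = czm, _["zt"] = czt,
    _["parent_mean_fitness"] = fit_sum / N,
    _["parent_min_fitness"] = fit_min,
    _["parent_mean_zygote_load"] = load_sum / N,
    _["uniform_fallback"] = fallback);
}

// Develop and age a batch of organisms that share all parameters, returning
// each adult's fitness and (optionally) one uniformly chosen germ cell.
// Used by the development-level experiments (adult fitness vs zygote load).
// [[Rcpp::export]]
List cpp_develop_batch(IntegerVector zm, int zt, int M, int L, int T,
                       int NG, int A, int S, double muS, double muB,
                       double s, double xi, double eps) {
  int n = zm.size();
  NumericVector fitness(n);
  IntegerVector germ_m(n), germ_tot(n);
  NumericVector tissue_var(n);
  Adult a;
  for (int i = 0; i < n; ++i) {
    develop_age_one(zm[i], zt, M, L, NG, A, S, muS, muB, a);
    fitness[i] = adult_fitness_cpp(a.cells, a.cell_total, T, s, xi, eps);
    int g = draw_index(static_cast<int>(a.germ.size()));
    germ_m[i] = a.germ[g];
    germ_tot[i] = a.germ_total;
    // between-tissue variance of tissue fitness
    int ntis = 1 << T, per = static_cast<int>(a.cells.size()) / ntis;
    double mean = 0.0;
    std::vector<double> tf(ntis);
    for (int t = 0; t < ntis; ++t) {
      double acc = 0.0;
      for (int c = t * per; c < (t + 1) * per; ++c)
        acc += 1.0 - s * std::pow(static_cast<double>(a.cells[c]) /
                                  a.cell_total, xi);
      tf[t] = acc / per;
      mean += tf[t];
    }
    mean /= ntis;
    double v = 0.0;
    for (int t = 0; t < ntis; ++t) v += (tf[t] - mean) * (tf[t] - mean);
    tissue_var[i] = ntis > 1 ? v / (ntis - 1) : 0.0;
  }
  return List::create(_["fitness"] = fitness, _["germ_m"] = germ_m,
                      _["germ_total"] = germ_tot,
                      _["tissue_var"] = tissue_var);
}
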