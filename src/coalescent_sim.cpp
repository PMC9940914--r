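// Monte Carlo genealogy simulators for the coalescent families supported by
// the package: Kingman with exponential growth, haploid Lambda-Beta(2-a,a),
// diploid Xi-Beta(2-a,a) (participants split across four parental
// chromosomes), and the Durrett-Schweinsberg (DS) recurrent-sweep coalescent,
// plus the restricted two-locus, two-sample DS extension.
//
// All randomness comes from R's RNG, so set.seed() in R makes every run
// reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// model codes shared with the R side
// 0 = Kingman (+growth), 1 = Lambda-Beta, 2 = Xi-Beta diploid, 3 = DS

struct RateTable {
  // cumw[b][k-2] = cumulative sum of choose(b,k)*lambda_{b,k} for k = 2..b
  std::vector<std::vector<double> > cumw;
  std::vector<double> q;  // total rate from b blocks (Lambda part only)
  int n;
};

RateTable make_table(int model, int n, double alpha, double cpar) {
  RateTable t;
  t.n = n;
  t.cumw.assign(n + 1, std::vector<double>());
  t.q.assign(n + 1, 0.0);
  const double lB0 =
      (model == 1 || model == 2) ? R::lbeta(2.0 - alpha, alpha) : 0.0;
  for (int b = 2; b <= n; ++b) {
    std::vector<double> cw(b - 1);
    double tot = 0.0;
    for (int k = 2; k <= b; ++k) {
      double lam;
      if (model == 0) {
        lam = (k == 2) ? 1.0 : 0.0;
      } else if (model == 1 || model == 2) {
        // lambda_{b,k} = B(k - alpha, b - k + alpha) / B(2 - alpha, alpha)
        lam = std::exp(R::lbeta(k - alpha, b - k + alpha) - lB0);
      } else {
        // DS: Kingman atom + c * B(k, b - k + 1)
        lam = ((k == 2) ? 1.0 : 0.0) +
              cpar * std::exp(R::lbeta((double)k, (double)(b - k + 1)));
      }
      tot += std::exp(R::lchoose((double)b, (double)k)) * lam;
      cw[k - 2] = tot;
    }
    t.cumw[b] = cw;
    t.q[b] = tot;
  }
  return t;
}

int sample_k(const std::vector<double> &cw) {
  double u = unif_rand() * cw.back();
  int lo = 0, hi = (int)cw.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cw[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo + 2;
}

// waiting time when the instantaneous rate is q * exp(g * s), current time t
double wait_time(double q, double g, double t) {
  double E = exp_rand();
  if (g == 0.0) return E / q;
  return std::log(std::exp(g * t) + g * E / q) / g - t;
}

void pick_distinct(int b, int k, std::vector<int> &idx, std::vector<int> &pool) {
  pool.resize(b);
  for (int i = 0; i < b; ++i) pool[i] = i;
  idx.resize(k);
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (b - i));
    if (j > b - 1) j = b - 1;
    std::swap(pool[i], pool[j]);
    idx[i] = pool[i];
  }
}

// remove positions listed in `rem` (must be sorted ascending) by swap-pop
void swap_pop(std::vector<int> &v, std::vector<int> &rem) {
  for (int i = (int)rem.size() - 1; i >= 0; --i) {
    v[rem[i]] = v.back();
    v.pop_back();
  }
}

// single Lambda-type genealogy (Kingman, Lambda-Beta, DS); accumulates the
// family-size branch-length spectrum into B (length n-1) and returns the TMRCA
double sim_lambda_one(const RateTable &tab, double g, double f_rate, int n,
                      double *B) {
  std::vector<int> sizes(n, 1);
  std::vector<int> idx, pool;
  double t = 0.0;
  while ((int)sizes.size() > 1) {
    int b = (int)sizes.size();
    double q = tab.q[b] + f_rate;
    double dt = wait_time(q, g, t);
    for (int i = 0; i < b; ++i) B[sizes[i] - 1] += dt;
    t += dt;
    if (f_rate > 0.0 && unif_rand() * q >= tab.q[b]) {
      // genome-wide sweep: every lineage is captured
      sizes.assign(1, n);
      break;
    }
    int k = sample_k(tab.cumw[b]);
    pick_distinct(b, k, idx, pool);
    std::sort(idx.begin(), idx.end());
    int tot = 0;
    for (size_t i = 0; i < idx.size(); ++i) tot += sizes[idx[i]];
    sizes[idx[0]] = tot;
    std::vector<int> rem(idx.begin() + 1, idx.end());
    swap_pop(sizes, rem);
  }
  return t;
}

// single diploid Xi-Beta genealogy: j participants drawn with the Lambda-Beta
// participant law, assigned uniformly to 4 parental chromosomes, each group of
// size >= 2 merges; events with no such group are null (thinning)
double sim_xi_one(const RateTable &tab, double g, int n, double *B) {
  std::vector<int> sizes(n, 1);
  std::vector<int> idx, pool;
  double t = 0.0;
  while ((int)sizes.size() > 1) {
    int b = (int)sizes.size();
    double dt = wait_time(tab.q[b], g, t);
    for (int i = 0; i < b; ++i) B[sizes[i] - 1] += dt;
    t += dt;
    int j = sample_k(tab.cumw[b]);
    pick_distinct(b, j, idx, pool);
    std::vector<int> groups[4];
    for (int i = 0; i < j; ++i) {
      int gi = (int)(unif_rand() * 4.0);
      if (gi > 3) gi = 3;
      groups[gi].push_back(idx[i]);
    }
    std::vector<int> rem;
    for (int gi = 0; gi < 4; ++gi) {
      if (groups[gi].size() >= 2) {
        int tot = 0;
        for (size_t z = 0; z < groups[gi].size(); ++z) tot += sizes[groups[gi][z]];
        sizes[groups[gi][0]] = tot;
        for (size_t z = 1; z < groups[gi].size(); ++z) rem.push_back(groups[gi][z]);
      }
    }
    std::sort(rem.begin(), rem.end());
    swap_pop(sizes, rem);
  }
  return t;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sim_spectra_cpp(int model, int n, int reps, double alpha,
                              double beta, double cpar, double f) {
  double g = 0.0, f_rate = 0.0, clocal = cpar;
  if (model == 0) g = beta;
  else if (model == 1 || model == 2) g = (alpha - 1.0) * beta;
  else if (model == 3) { clocal = (1.0 - f) * cpar; f_rate = f * cpar; }
  RateTable tab = make_table(model, n, alpha, clocal);
  NumericMatrix out(reps, n);  // columns 1..n-1: B_i; column n: TMRCA
  std::vector<double> B(n - 1);
  for (int r = 0; r < reps; ++r) {
    std::fill(B.begin(), B.end(), 0.0);
    double tm = (model == 2) ? sim_xi_one(tab, g, n, B.data())
                             : sim_lambda_one(tab, g, f_rate, n, B.data());
    for (int i = 0; i < n - 1; ++i) out(r, i) = B[i];
    out(r, n - 1) = tm;
  }
  return out;
}

// Single genealogy with a full event record: for each event the time and the
// list of merging groups (block ids). Block ids 1..n are the leaves; merged
// blocks receive fresh ids n+1, n+2, ...
// [[Rcpp::export]]
List sim_genealogy_cpp(int model, int n, double alpha, double beta,
                       double cpar, double f) {
  double g = 0.0, f_rate = 0.0, clocal = cpar;
  if (model == 0) g = beta;
  else if (model == 1 || model == 2) g = (alpha - 1.0) * beta;
  else if (model == 3) { clocal = (1.0 - f) * cpar; f_rate = f * cpar; }
  RateTable tab = make_table(model, n, alpha, clocal);

  std::vector<int> ids(n), sizes(n, 1), idx, pool;
  for (int i = 0; i < n; ++i) ids[i] = i + 1;
  int next_id = n + 1;
  double t = 0.0;
  std::vector<double> times;
  List events;
  List new_ids;

  while ((int)sizes.size() > 1) {
    int b = (int)sizes.size();
    double q = tab.q[b] + f_rate;
    t += wait_time(q, g, t);

    std::vector<std::vector<int> > merged;  // groups of merging block ids
    if (model == 3 && f_rate > 0.0 && unif_rand() * q >= tab.q[b]) {
      merged.push_back(ids);
      ids.assign(1, next_id);
      sizes.assign(1, n);
      ++next_id;
    } else if (model == 2) {
      int j = sample_k(tab.cumw[b]);
      pick_distinct(b, j, idx, pool);
      std::vector<int> groups[4];
      for (int i = 0; i < j; ++i) {
        int gi = (int)(unif_rand() * 4.0);
        if (gi > 3) gi = 3;
        groups[gi].push_back(idx[i]);
      }
      std::vector<int> rem;
      for (int gi = 0; gi < 4; ++gi) {
        if (groups[gi].size() >= 2) {
          std::vector<int> grp_ids;
          int tot = 0;
          for (size_t z = 0; z < groups[gi].size(); ++z) {
            grp_ids.push_back(ids[groups[gi][z]]);
            tot += sizes[groups[gi][z]];
          }
          merged.push_back(grp_ids);
          ids[groups[gi][0]] = next_id++;
          sizes[groups[gi][0]] = tot;
          for (size_t z = 1; z < groups[gi].size(); ++z) rem.push_back(groups[gi][z]);
        }
      }
      std::sort(rem.begin(), rem.end());
      swap_pop(sizes, rem);
      swap_pop(ids, rem);
      if (merged.empty()) continue;  // null event, nothing merged
    } else {
      int k = sample_k(tab.cumw[b]);
      pick_distinct(b, k, idx, pool);
      std::sort(idx.begin(), idx.end());
      std::vector<int> grp_ids;
      int tot = 0;
      for (size_t i = 0; i < idx.size(); ++i) {
        grp_ids.push_back(ids[idx[i]]);
        tot += sizes[idx[i]];
      }
      merged.push_back(grp_ids);
      ids[idx[0]] = next_id++;
      sizes[idx[0]] = tot;
      std::vector<int> rem(idx.begin() + 1, idx.end());
      swap_pop(sizes, rem);
      swap_pop(ids, rem);
    }

    times.push_back(t);
    List ev(merged.size());
    IntegerVector nid(merged.size());
    for (size_t z = 0; z < merged.size(); ++z) {
      ev[z] = wrap(merged[z]);
      nid[z] = next_id - (int)merged.size() + (int)z;
    }
    events.push_back(ev);
    new_ids.push_back(nid);
  }

  return List::create(_["n"] = n, _["times"] = wrap(times),
                      _["events"] = events, _["new_ids"] = new_ids,
                      _["tmrca"] = t);
}

// Two-locus, two-sample DS extension. Lineages carry ancestral material for
// locus A (bit 1) and/or locus B (bit 2). Background: Kingman coalescence
// (rate 1 per pair) and recombination (rate d/2 per lineage carrying both
// loci, d in scaled map units). Sweeps arrive at rate c * L with position
// uniform on a window of length L = d + 2 * margin; intensity y has density
// 2y on (0,1); lineage copies of locus l are captured when a shared uniform
// falls below y * exp(-|x - p_l|); captured copies of a locus coalesce.
// With probability f a sweep is genome-wide and captures everything.
// [[Rcpp::export]]
List sim_two_locus_cpp(double cpar, double f, double d, int reps,
                       double margin) {
  double L = d + 2.0 * margin;
  double pA = margin, pB = margin + d;
  // local sweeps arrive per unit map length; genome-wide sweeps at constant
  // rate f * c so the long-distance correlation plateau does not depend on
  // the window size
  double local_rate = (cpar > 0.0) ? (1.0 - f) * cpar * L : 0.0;
  double gw_rate = (cpar > 0.0) ? f * cpar : 0.0;
  double sweep_rate = local_rate + gw_rate;
  double rec_per = d / 2.0;
  NumericVector TA(reps), TB(reps);

  for (int r = 0; r < reps; ++r) {
    std::vector<int> lin;
    lin.push_back(3);
    lin.push_back(3);
    double t = 0.0, tA = -1.0, tB = -1.0;
    while (tA < 0.0 || tB < 0.0) {
      int m = (int)lin.size();
      int ndouble = 0;
      for (int i = 0; i < m; ++i) if (lin[i] == 3) ++ndouble;
      double rc = 0.5 * m * (m - 1);
      double rr = ndouble * rec_per;
      double q = rc + rr + sweep_rate;
      t += exp_rand() / q;
      double u = unif_rand() * q;
      int coalesced = 0;  // bits of loci that found their MRCA this event
      if (u < rc) {
        int i = (int)(unif_rand() * m);
        if (i > m - 1) i = m - 1;
        int j = (int)(unif_rand() * (m - 1));
        if (j > m - 2) j = m - 2;
        if (j >= i) ++j;
        coalesced = lin[i] & lin[j];
        lin[i] |= lin[j];
        lin[j] = lin.back();
        lin.pop_back();
      } else if (u < rc + rr) {
        int pick = (int)(unif_rand() * ndouble);
        if (pick > ndouble - 1) pick = ndouble - 1;
        for (int i = 0, seen = 0; i < m; ++i) {
          if (lin[i] == 3 && seen++ == pick) {
            lin[i] = 1;
            lin.push_back(2);
            break;
          }
        }
      } else {
        if (gw_rate > 0.0 && unif_rand() * sweep_rate < gw_rate) {
          coalesced = 3;  // genome-wide sweep captures all material
          lin.assign(1, 0);
        } else {
          double y = std::sqrt(unif_rand());
          double x = unif_rand() * L;
          double capA = y * std::exp(-std::fabs(x - pA));
          double capB = y * std::exp(-std::fabs(x - pB));
          int nA = 0, nB = 0;
          for (int i = 0; i < (int)lin.size(); ++i) {
            double u2 = unif_rand();
            int moved = 0;
            if ((lin[i] & 1) && u2 < capA) moved |= 1;
            if ((lin[i] & 2) && u2 < capB) moved |= 2;
            lin[i] &= ~moved;
            if (moved & 1) ++nA;
            if (moved & 2) ++nB;
          }
          if (nA == 2) coalesced |= 1;
          if (nB == 2) coalesced |= 2;
          int sw = ((nA == 1) ? 1 : 0) | ((nB == 1) ? 2 : 0);
          if (sw) lin.push_back(sw);
        }
      }
      if ((coalesced & 1) && tA < 0.0) tA = t;
      if ((coalesced & 2) && tB < 0.0) tB = t;
      // strip material of coalesced loci and drop empty lineages
      int done = ((tA >= 0.0) ? 1 : 0) | ((tB >= 0.0) ? 2 : 0);
      if (done) {
        size_t w = 0;
        for (size_t i = 0; i < lin.size(); ++i) {
          int v = lin[i] & ~done;
          if (v) lin[w++] = v;
        }
        lin.resize(w);
      }
    }
    TA[r] = tA;
    TB[r] = tB;
  }
  return List::create(_["TA"] = TA, _["TB"] = TB);
}
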