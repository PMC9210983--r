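// Structured coalescent simulator with recombination.
//
// Lineages carry lists of ancestral-material segments on [0, L); each segment
// stores the set of sample leaves descending from it (bitmask, <= 128 leaves).
// Events compete as independent exponential clocks: within-population
// coalescence (piecewise-exponential population sizes, inverted analytically),
// migration, recombination (rate proportional to the span of ancestral
// material), and infinite-sites mutation (rate proportional to the total
// ancestral length). Segments whose leaf set reaches the full sample are the
// grand MRCA for that material and are dropped. Time is measured in units of
// 2*N_ref generations.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
#include <random>

using namespace Rcpp;

typedef std::array<uint64_t, 2> Mask;

static inline bool mask_eq(const Mask& a, const Mask& b) {
  return a[0] == b[0] && a[1] == b[1];
}
static inline Mask mask_or(const Mask& a, const Mask& b) {
  Mask m;
  m[0] = a[0] | b[0];
  m[1] = a[1] | b[1];
  return m;
}
static inline int mask_count(const Mask& a, const Mask& b) {
  return __builtin_popcountll(a[0] & b[0]) + __builtin_popcountll(a[1] & b[1]);
}

struct Seg {
  double l, r;
  Mask m;
};

struct Lin {
  std::vector<Seg> segs;
  int pop;
  double span() const {
    return segs.empty() ? 0.0 : (segs.back().r - segs.front().l);
  }
  double tot() const {
    double s = 0.0;
    for (const Seg& g : segs) s += g.r - g.l;
    return s;
  }
};

struct Mut {
  double pos;
  Mask m;
};

// Merge two sorted segment lists; overlapping stretches take the union of the
// leaf sets; stretches whose union equals the full sample set have coalesced
// completely and are discarded.
static std::vector<Seg> merge_segs(const std::vector<Seg>& A,
                                   const std::vector<Seg>& B,
                                   const Mask& full) {
  std::vector<Seg> out;
  out.reserve(A.size() + B.size());
  auto push = [&](double l, double r, const Mask& m) {
    if (r <= l) return;
    if (mask_eq(m, full)) return;
    if (!out.empty() && out.back().r == l && mask_eq(out.back().m, m)) {
      out.back().r = r;
    } else {
      out.push_back({l, r, m});
    }
  };
  size_t i = 0, j = 0;
  Seg a, b;
  bool ha = false, hb = false;
  for (;;) {
    if (!ha && i < A.size()) { a = A[i++]; ha = true; }
    if (!hb && j < B.size()) { b = B[j++]; hb = true; }
    if (!ha && !hb) break;
    if (ha && !hb) { push(a.l, a.r, a.m); ha = false; continue; }
    if (hb && !ha) { push(b.l, b.r, b.m); hb = false; continue; }
    if (a.r <= b.l) { push(a.l, a.r, a.m); ha = false; continue; }
    if (b.r <= a.l) { push(b.l, b.r, b.m); hb = false; continue; }
    if (a.l < b.l) { push(a.l, b.l, a.m); a.l = b.l; }
    else if (b.l < a.l) { push(b.l, a.l, b.m); b.l = a.l; }
    double r = std::min(a.r, b.r);
    push(a.l, r, mask_or(a.m, b.m));
    a.l = r;
    b.l = r;
    if (a.r <= a.l) ha = false;
    if (b.r <= b.l) hb = false;
  }
  return out;
}

// Waiting time to the next coalescence in a population whose inverse size grows
// as exp(beta * (t - t_e)) / nu_e within the epoch (beta > 0: population was
// smaller in the past). Returns R_PosInf when the event cannot happen.
static double coal_wait(double k2, double nu_e, double beta, double tau,
                        double E) {
  if (k2 <= 0.0) return R_PosInf;
  if (beta == 0.0) return E * nu_e / k2;
  double rhs = std::exp(beta * tau) + E * beta * nu_e / k2;
  if (rhs <= 0.0) return R_PosInf;
  return std::log(rhs) / beta - tau;
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector n_by_pop, double L, NumericVector rho_bp,
                  double theta_bp, NumericVector epoch_times, NumericMatrix nu,
                  NumericMatrix beta, NumericVector mig, IntegerMatrix merges,
                  int n_reps, int mode) {
  const int P = n_by_pop.size();
  const int E = epoch_times.size();
  const int n_tot = std::accumulate(n_by_pop.begin(), n_by_pop.end(), 0);
  if (n_tot < 2) stop("need at least two sampled lineages");
  if (n_tot > 128) stop("at most 128 haploid lineages are supported");

  Mask full{0, 0};
  for (int i = 0; i < n_tot; ++i) full[i >> 6] |= (uint64_t)1 << (i & 63);

  // per-population leaf masks (leaves laid out pop by pop)
  std::vector<Mask> pop_mask(P, Mask{0, 0});
  {
    int idx = 0;
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < n_by_pop[p]; ++i, ++idx)
        pop_mask[p][idx >> 6] |= (uint64_t)1 << (idx & 63);
  }

  // mig[i + P*j + P*P*e]: backward rate for a lineage in pop i to jump to j
  auto mig_rate = [&](int e, int i, int j) { return mig[i + P * j + P * P * e]; };

  // Migration randomness uses a private stream (seeded once from the main R
  // stream) so that models differing only in migration rates share the main
  // event stream exactly when no migration event fires: common random numbers
  // then cancel between nested model fits.
  std::mt19937_64 mig_rng((uint64_t)(unif_rand() * 9007199254740992.0));
  std::exponential_distribution<double> mig_exp(1.0);
  std::uniform_real_distribution<double> mig_unif(0.0, 1.0);

  const int n0 = P > 0 ? n_by_pop[0] : 0;
  const int n1 = P > 1 ? n_by_pop[1] : 0;
  NumericMatrix sfs(n0 + 1, n1 + 1);
  NumericMatrix sfs_sq(mode == 2 ? n0 + 1 : 1, mode == 2 ? n1 + 1 : 1);
  NumericMatrix rep_sfs(mode == 2 ? n0 + 1 : 1, mode == 2 ? n1 + 1 : 1);
  double tot_sum = 0.0, tot_sumsq = 0.0;
  IntegerVector s_out(n_reps);
  NumericVector tmrca_out(n_reps);
  List reps(mode == 0 ? n_reps : 0);

  for (int rep = 0; rep < n_reps; ++rep) {
    double rho = rho_bp.size() == 1 ? rho_bp[0] : rho_bp[rep];

    std::vector<Lin> lins;
    lins.reserve(2 * n_tot);
    std::vector<int> kpop(P, 0);
    {
      int idx = 0;
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < n_by_pop[p]; ++i, ++idx) {
          Mask m{0, 0};
          m[idx >> 6] |= (uint64_t)1 << (idx & 63);
          Lin ln;
          ln.segs.push_back({0.0, L, m});
          ln.pop = p;
          lins.push_back(ln);
          kpop[p]++;
        }
    }

    std::vector<Mut> muts;
    double t = 0.0;
    int e = 0;
    long iter = 0;
    const long max_iter = 50000000L;

    while (!lins.empty()) {
      if (++iter > max_iter) stop("simulation did not coalesce (event cap hit)");
      double t_e = epoch_times[e];
      double t_next = (e + 1 < E) ? epoch_times[e + 1] : R_PosInf;
      double tau = t - t_e;

      // candidate: coalescence per population
      double s_coal = R_PosInf;
      int coal_pop = -1;
      for (int p = 0; p < P; ++p) {
        if (kpop[p] < 2) continue;
        double k2 = 0.5 * kpop[p] * (kpop[p] - 1);
        double s = coal_wait(k2, nu(e, p), beta(e, p), tau, exp_rand());
        if (s < s_coal) { s_coal = s; coal_pop = p; }
      }

      // candidate: migration
      std::vector<double> outrate(P, 0.0);
      double migtot = 0.0;
      for (int p = 0; p < P; ++p) {
        for (int j = 0; j < P; ++j)
          if (j != p) outrate[p] += mig_rate(e, p, j);
        migtot += kpop[p] * outrate[p];
      }
      double s_mig = migtot > 0.0 ? mig_exp(mig_rng) / migtot : R_PosInf;

      // candidate: recombination and mutation
      double span_sum = 0.0, tot_sum = 0.0;
      if (rho > 0.0 || theta_bp > 0.0) {
        for (const Lin& ln : lins) {
          span_sum += ln.span();
          tot_sum += ln.tot();
        }
      }
      double rrate = 0.5 * rho * span_sum;
      double urate = 0.5 * theta_bp * tot_sum;
      double s_rec = rrate > 0.0 ? exp_rand() / rrate : R_PosInf;
      double s_mut = urate > 0.0 ? exp_rand() / urate : R_PosInf;

      double s_min = std::min(std::min(s_coal, s_mig), std::min(s_rec, s_mut));
      if (mode == 2) {
        // accumulate expected branch length per joint frequency class
        // (Rao-Blackwellized SFS: no mutation noise)
        double dt = std::min(s_min, t_next - t);
        if (R_FINITE(dt) && dt > 0.0) {
          for (const Lin& ln : lins)
            for (const Seg& g : ln.segs) {
              int i = mask_count(g.m, pop_mask[0]);
              int j = P > 1 ? mask_count(g.m, pop_mask[1]) : 0;
              rep_sfs(i, j) += dt * (g.r - g.l);
            }
        }
      }
      if (t + s_min >= t_next) {
        if (!R_FINITE(t_next))
          stop("lineages cannot coalesce under this demography");
        t = t_next;
        ++e;
        for (int r = 0; r < merges.nrow(); ++r) {
          if (merges(r, 0) == e) {
            int from = merges(r, 1), to = merges(r, 2);
            for (Lin& ln : lins)
              if (ln.pop == from) ln.pop = to;
            kpop[to] += kpop[from];
            kpop[from] = 0;
          }
        }
        continue;
      }
      t += s_min;

      if (s_min == s_mut) {
        // choose lineage weighted by total ancestral length, then a segment
        double u = unif_rand() * tot_sum, acc = 0.0;
        for (Lin& ln : lins) {
          double w = ln.tot();
          if (u < acc + w) {
            double v = u - acc;
            for (const Seg& g : ln.segs) {
              double len = g.r - g.l;
              if (v < len) {
                muts.push_back({g.l + v, g.m});
                break;
              }
              v -= len;
            }
            break;
          }
          acc += w;
        }
      } else if (s_min == s_rec) {
        double u = unif_rand() * span_sum, acc = 0.0;
        for (size_t li = 0; li < lins.size(); ++li) {
          double w = lins[li].span();
          if (u < acc + w) {
            Lin& ln = lins[li];
            double x = ln.segs.front().l + (u - acc);
            Lin right;
            right.pop = ln.pop;
            std::vector<Seg> left;
            for (const Seg& g : ln.segs) {
              if (g.r <= x) left.push_back(g);
              else if (g.l >= x) right.segs.push_back(g);
              else {
                left.push_back({g.l, x, g.m});
                right.segs.push_back({x, g.r, g.m});
              }
            }
            if (!right.segs.empty() && !left.empty()) {
              ln.segs = left;
              lins.push_back(right);
              kpop[right.pop]++;
            }
            break;
          }
          acc += w;
        }
      } else if (s_min == s_mig) {
        double u = mig_unif(mig_rng) * migtot, acc = 0.0;
        for (Lin& ln : lins) {
          double w = outrate[ln.pop];
          if (u < acc + w) {
            double v = u - acc;
            for (int j = 0; j < P; ++j) {
              if (j == ln.pop) continue;
              double r = mig_rate(e, ln.pop, j);
              if (v < r) {
                kpop[ln.pop]--;
                ln.pop = j;
                kpop[j]++;
                j = P;
              } else v -= r;
            }
            break;
          }
          acc += w;
        }
      } else {
        // coalescence in coal_pop: draw an unordered pair uniformly
        int k = kpop[coal_pop];
        int a = (int)(unif_rand() * k);
        int b = (int)(unif_rand() * (k - 1));
        if (b >= a) ++b;
        if (a >= k) a = k - 1;
        if (b >= k) b = a == k - 1 ? k - 2 : k - 1;
        int ia = -1, ib = -1, seen = 0;
        for (size_t li = 0; li < lins.size(); ++li) {
          if (lins[li].pop == coal_pop) {
            if (seen == a) ia = (int)li;
            if (seen == b) ib = (int)li;
            ++seen;
          }
        }
        Lin merged;
        merged.pop = coal_pop;
        merged.segs = merge_segs(lins[ia].segs, lins[ib].segs, full);
        // remove the two parents (higher index first), add the child if it
        // still carries uncoalesced material
        int hi = std::max(ia, ib), lo = std::min(ia, ib);
        lins[hi] = lins.back(); lins.pop_back();
        lins[lo] = lins.back(); lins.pop_back();
        kpop[coal_pop] -= 2;
        if (!merged.segs.empty()) {
          lins.push_back(merged);
          kpop[coal_pop]++;
        }
        if (lins.empty()) tmrca_out[rep] = t;
      }
    }
    if (tmrca_out[rep] == 0.0) tmrca_out[rep] = t;

    std::sort(muts.begin(), muts.end(),
              [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
    s_out[rep] = (int)muts.size();

    if (mode == 2) {
      // fold the replicate into first and second moments (for downstream
      // variance-based bias correction of log-probabilities)
      double tr = 0.0;
      for (int i = 0; i <= n0; ++i)
        for (int j = 0; j <= n1; ++j) {
          double x = rep_sfs(i, j);
          if (x > 0.0) {
            sfs(i, j) += x;
            sfs_sq(i, j) += x * x;
            tr += x;
            rep_sfs(i, j) = 0.0;
          }
        }
      tot_sum += tr;
      tot_sumsq += tr * tr;
    }
    if (mode == 1) {
      for (const Mut& m : muts) {
        int i = mask_count(m.m, pop_mask[0]);
        int j = P > 1 ? mask_count(m.m, pop_mask[1]) : 0;
        sfs(i, j) += 1.0;
      }
    } else if (mode == 0) {
      int S = (int)muts.size();
      NumericVector pos(S);
      IntegerMatrix hap(n_tot, S);
      for (int s = 0; s < S; ++s) {
        pos[s] = muts[s].pos;
        for (int i = 0; i < n_tot; ++i)
          if (muts[s].m[i >> 6] & ((uint64_t)1 << (i & 63))) hap(i, s) = 1;
      }
      reps[rep] = List::create(_["positions"] = pos, _["haplotypes"] = hap,
                               _["tmrca"] = tmrca_out[rep]);
    }
  }

  if (mode == 2)
    return List::create(_["sfs"] = sfs, _["sfs_sq"] = sfs_sq,
                        _["tot_sum"] = tot_sum, _["tot_sumsq"] = tot_sumsq,
                        _["n_seg"] = s_out, _["tmrca"] = tmrca_out);
  if (mode == 1)
    return List::create(_["sfs"] = sfs, _["n_seg"] = s_out,
                        _["tmrca"] = tmrca_out);
  return List::create(_["reps"] = reps, _["n_seg"] = s_out,
                      _["tmrca"] = tmrca_out);
}
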