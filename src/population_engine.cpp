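#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Agent-based stem-cell population engine.
//
// Each agent carries: age (h since birth), active-Rb level r, a
// commitment time drawn at birth (exponential, mean tau_d), a feedback
// sensitivity alpha, and a clone id. Per step (Euler-Maruyama, step dt):
//   1. count live cells N; per-cell control parameter C_i from the
//      feedback variant evaluated at the perceived size alpha_i * N
//      (or alpha_i * D for the differentiated-pool variant);
//   2. update each r_i by one Ito Euler-Maruyama step, clip at 0;
//   3. increment ages;
//   4. fate clocks ("competing risks"):
//      RD: a cell whose age reaches its commitment time differentiates
//          (leaves) at that moment; any division (r_i < r_thresh, or the
//          baseline event with prob dt/T_baseline) is therefore a
//          self-renewal.
//      DR: fate is resolved at division: age < commitment ->
//          differentiation (cell leaves), age >= commitment -> renewal.
//   5. a renewing division resets the parent (age 0, r = r0, fresh
//      commitment draw) and creates a daughter; the daughter's alpha is
//      mutated with probability p_m by a log-normal factor (log-sd
//      sigma_mut), clipped below at alpha_min, and starts a new clone.
//   6. optional differentiated pool D: gains cells from differentiation
//      events, decays at rate gamma_pool.
//
// Feedback variants: 0 -> C = fbA / (alpha*N)   (hyperbolic, RD-paired)
//                    1 -> C = fbA * (alpha*N)   (linear, DR-paired)
//                    2 -> differentiated pool: basal niche mitogen plus a
//                         contribution proportional to the perceived pool,
//                         C = C_basal + (fbA - C_basal) * alpha*D/D_st.
//                         The basal term keeps slow cycling alive when the
//                         pool is depleted, so the differentiation flux can
//                         refill it (no absorbing collapsed state).
// fbA is precomputed in R. Uses R's RNG, so set.seed() in R governs
// reproducibility.

// [[Rcpp::export(name = ".pop_engine")]]
List pop_engine(int n0, int capacity, bool grow,
                int topology, int fb_variant, double fbA,
                double gamma_D, double V, double k1, double k2,
                double sigma, double r0, double r_thresh,
                double dt, double t_max, double tau_d, double T_baseline,
                double p_m, double sigma_mut, double alpha_min,
                bool use_D, double gamma_pool, double D0, double warmup,
                double D_st, double C_basal,
                int record_every) {
  int n_step = (int) std::ceil(t_max / dt);
  int n_rec = n_step / record_every + 1;

  std::vector<char> active(capacity, 0);
  std::vector<double> age(capacity, 0.0), r(capacity, 0.0),
      commit(capacity, 0.0), alpha(capacity, 1.0);
  std::vector<int> clone(capacity, 0);
  std::vector<int> free_slots;
  free_slots.reserve(capacity);
  for (int i = capacity - 1; i >= n0; --i) free_slots.push_back(i);
  for (int i = 0; i < n0; ++i) {
    active[i] = 1;
    r[i] = r0;
    commit[i] = exp_rand() * tau_d;
    clone[i] = 0;
  }
  int next_clone = 1;
  int n_live = n0;
  double D = D0;

  std::vector<double> rec_t, rec_N, rec_alpha, rec_D;
  std::vector<int> rec_renew, rec_diff;
  rec_t.reserve(n_rec); rec_N.reserve(n_rec); rec_alpha.reserve(n_rec);
  rec_D.reserve(n_rec); rec_renew.reserve(n_rec); rec_diff.reserve(n_rec);

  bool extinct = false;
  double extinction_time = NA_REAL;
  int acc_renew = 0, acc_diff = 0;
  double acc_age_div = 0.0;   // summed cycle length (age) at fate events
  std::vector<double> rec_age_div;
  rec_age_div.reserve(n_rec);
  double sqdt = std::sqrt(dt);
  double p_base = dt / T_baseline;
  std::vector<int> snapshot;
  snapshot.reserve(capacity);

  // record initial state
  {
    double asum = 0.0;
    for (int i = 0; i < capacity; ++i) if (active[i]) asum += alpha[i];
    rec_t.push_back(0.0); rec_N.push_back(n_live);
    rec_alpha.push_back(n_live > 0 ? asum / n_live : NA_REAL);
    rec_D.push_back(D); rec_renew.push_back(0); rec_diff.push_back(0);
    rec_age_div.push_back(0.0);
  }

  for (int k = 1; k <= n_step; ++k) {
    if (n_live == 0) { extinct = true; extinction_time = (k - 1) * dt; break; }
    int N = n_live;
    snapshot.clear();
    for (int i = 0; i < (int) active.size(); ++i)
      if (active[i]) snapshot.push_back(i);

    int n_diff_step = 0;
    for (size_t s = 0; s < snapshot.size(); ++s) {
      int i = snapshot[s];
      if (!active[i]) continue;  // removed earlier this step (never happens
                                 // with snapshot order, kept as a guard)
      // feedback with this cell's sensitivity
      double perceived = alpha[i] * (fb_variant == 2 ? D : (double) N);
      if (perceived < 1e-12) perceived = 1e-12;
      double C;
      if (fb_variant == 0) C = fbA / perceived;
      else if (fb_variant == 1) C = fbA * perceived;
      else C = C_basal + (fbA - C_basal) * perceived / D_st;
      if (C < 0) C = 0;
      // Euler-Maruyama update of r
      double ri = r[i];
      double Ceff = C / (1.0 + C / k1);
      double gp = V * Ceff / (1.0 + (ri / k2) * (ri / k2));
      ri += (1.0 - (gamma_D + gp) * ri) * dt + sigma * ri * sqdt * norm_rand();
      if (ri < 0) ri = 0;
      r[i] = ri;
      age[i] += dt;

      // warm-up: cells cycle (divisions reset the parent) but fates are
      // frozen -- no births, no removals, pool clamped -- so the initially
      // synchronised cohort spreads over the cycle before feedback engages
      if (use_D && k * dt <= warmup) {
        if (ri < r_thresh || unif_rand() < p_base) {
          age[i] = 0.0; r[i] = r0; commit[i] = exp_rand() * tau_d;
        }
        continue;
      }
      bool renewed = false, differentiated = false;
      if (topology == 0 && age[i] >= commit[i]) {
        // RD: commitment clock fires first -> differentiate now
        differentiated = true;
      } else {
        bool divides = (ri < r_thresh) || (unif_rand() < p_base);
        if (divides) {
          if (topology == 0) {
            renewed = true;                       // RD: age < commit here
          } else {
            if (age[i] >= commit[i]) renewed = true;   // DR
            else differentiated = true;
          }
        }
      }

      if (differentiated) {
        acc_age_div += age[i];
        active[i] = 0;
        free_slots.push_back(i);
        --n_live;
        ++n_diff_step;
        if (use_D && k * dt > warmup) D += (topology == 0) ? 1.0 : 2.0;
        continue;
      }
      if (renewed) {
        acc_age_div += age[i];
        // reset parent
        age[i] = 0.0; r[i] = r0; commit[i] = exp_rand() * tau_d;
        // daughter
        if (free_slots.empty()) {
          if (!grow) stop("population exceeded capacity (grow = FALSE)");
          size_t old = active.size(), add = old;  // double the storage
          active.resize(old + add, 0);
          age.resize(old + add, 0.0); r.resize(old + add, 0.0);
          commit.resize(old + add, 0.0); alpha.resize(old + add, 1.0);
          clone.resize(old + add, 0);
          for (int j = (int) (old + add) - 1; j >= (int) old; --j)
            free_slots.push_back(j);
        }
        int d = free_slots.back(); free_slots.pop_back();
        active[d] = 1; age[d] = 0.0; r[d] = r0;
        commit[d] = exp_rand() * tau_d;
        double a_d = alpha[i];
        int cl_d = clone[i];
        if (p_m > 0 && unif_rand() < p_m) {
          a_d *= std::exp(sigma_mut * norm_rand());
          if (a_d < alpha_min) a_d = alpha_min;
          cl_d = next_clone++;
        }
        alpha[d] = a_d; clone[d] = cl_d;
        ++n_live;
        ++acc_renew;
      }
    }
    acc_diff += n_diff_step;
    // the differentiated pool is clamped at D0 during the warm-up window,
    // giving the cold-started (synchronised) stem cells time to establish
    // a differentiation flux before the pool evolves freely
    if (use_D && k * dt > warmup) D -= gamma_pool * D * dt;

    if (k % record_every == 0) {
      double asum = 0.0;
      for (int i = 0; i < (int) active.size(); ++i)
        if (active[i]) asum += alpha[i];
      rec_t.push_back(k * dt);
      rec_N.push_back(n_live);
      rec_alpha.push_back(n_live > 0 ? asum / n_live : NA_REAL);
      rec_D.push_back(D);
      rec_renew.push_back(acc_renew);
      rec_diff.push_back(acc_diff);
      rec_age_div.push_back(acc_age_div);
      acc_renew = 0; acc_diff = 0; acc_age_div = 0.0;
    }
  }
  if (n_live == 0 && !extinct) { extinct = true; extinction_time = n_step * dt; }

  // final per-cell state (live cells only)
  int nf = n_live;
  NumericVector f_age(nf), f_r(nf), f_commit(nf), f_alpha(nf);
  IntegerVector f_clone(nf);
  int j = 0;
  for (int i = 0; i < (int) active.size(); ++i) {
    if (active[i]) {
      f_age[j] = age[i]; f_r[j] = r[i]; f_commit[j] = commit[i];
      f_alpha[j] = alpha[i]; f_clone[j] = clone[i];
      ++j;
    }
  }
  return List::create(
      _["times"] = wrap(rec_t), _["N"] = wrap(rec_N),
      _["mean_alpha"] = wrap(rec_alpha), _["D"] = wrap(rec_D),
      _["renewals"] = wrap(rec_renew), _["differentiations"] = wrap(rec_diff),
      _["age_at_division_sum"] = wrap(rec_age_div),
      _["extinct"] = extinct, _["extinction_time"] = extinction_time,
      _["final_age"] = f_age, _["final_r"] = f_r,
      _["final_commit"] = f_commit, _["final_alpha"] = f_alpha,
      _["final_clone"] = f_clone);
}
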