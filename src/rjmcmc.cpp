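// Reversible-jump MCMC over the four-model Brownian family:
// BM (sigma2, alpha only), rBM1 (+ subtree rate shifts), jumpBM (+ mean
// jumps at branch starts), jumpRBM (both). A shift multiplies the rate of
// its branch and entire subtree; a jump displaces the mean of every tip
// descending from its branch. Uses R's RNG so chains are seed-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  int n_tip, n_all;
  std::vector<int> po_parent, po_child;   // postorder edges, 0-based node ids
  std::vector<double> po_len;
  std::vector<std::vector<int>> sub_edges; // per branch (child id): subtree branch ids
  std::vector<std::vector<int>> sub_tips;  // per branch: descendant tip ids
};

struct State {
  double sigma2, alpha;
  std::vector<double> mult;      // effective rate multiplier per branch
  std::vector<double> shift_m;   // multiplier of a shift on this branch (0 = none)
  std::vector<double> jump_s;    // jump size on this branch
  std::vector<bool> has_shift, has_jump;
  std::vector<double> tip_offset;
  int k_shift = 0, k_jump = 0;
  double loglik = 0.0;
};

double prune_loglik(const Tree& tr, const std::vector<double>& x,
                    const State& st) {
  const int n = tr.n_all;
  std::vector<double> xv(n, 0.0), sv(n, 0.0), px(n), pv(n);
  std::vector<bool> seen(n, false);
  for (int i = 0; i < tr.n_tip; ++i) xv[i] = x[i] - st.tip_offset[i];
  double ll = 0.0;
  const int ne = (int)tr.po_child.size();
  for (int e = 0; e < ne; ++e) {
    int ch = tr.po_child[e], p = tr.po_parent[e];
    double v = sv[ch] + st.sigma2 * st.mult[ch] * tr.po_len[e];
    if (!seen[p]) { px[p] = xv[ch]; pv[p] = v; seen[p] = true; }
    else {
      double V = pv[p] + v;
      if (V <= 0) return R_NegInf;
      double d = px[p] - xv[ch];
      ll += -0.5 * std::log(2.0 * M_PI * V) - d * d / (2.0 * V);
      xv[p] = (px[p] * v + xv[ch] * pv[p]) / V;
      sv[p] = pv[p] * v / V;
      seen[p] = false;
    }
  }
  int root = tr.n_tip;
  double V = sv[root];
  if (V <= 0) return R_NegInf;
  double d = xv[root] - st.alpha;
  ll += -0.5 * std::log(2.0 * M_PI * V) - d * d / (2.0 * V);
  return ll;
}

inline double jump_tau2(const State& st, double jump_c, double med_bl) {
  return jump_c * st.sigma2 * med_bl;
}

double jump_prior_logdens(const State& st, double jump_c, double med_bl) {
  double t2 = jump_tau2(st, jump_c, med_bl);
  double lp = 0.0;
  for (size_t b = 0; b < st.jump_s.size(); ++b)
    if (st.has_jump[b]) {
      double s = st.jump_s[b];
      lp += -0.5 * std::log(2.0 * M_PI * t2) - s * s / (2.0 * t2);
    }
  return lp;
}

void apply_shift_factor(const Tree& tr, State& st, int b, double factor) {
  for (int e : tr.sub_edges[b]) st.mult[e] *= factor;
}

void apply_jump_delta(const Tree& tr, State& st, int b, double delta) {
  for (int t : tr.sub_tips[b]) st.tip_offset[t] += delta;
}

int pick_branch(const std::vector<int>& pool) {
  int i = (int)std::floor(unif_rand() * pool.size());
  if (i >= (int)pool.size()) i = (int)pool.size() - 1;
  return pool[i];
}

} // namespace

// [[Rcpp::export(name = ".rjmcmc_run")]]
List rjmcmc_run(int n_tip, IntegerVector po_parent, IntegerVector po_child,
                NumericVector po_len, List sub_edges, List sub_tips,
                NumericVector traits, bool allow_shifts, bool allow_jumps,
                int ngen, int thin, double burnin_frac, double prop_width,
                double poisson_mean, double jump_c, double med_bl,
                double sigma2_init, double alpha_init) {
  Tree tr;
  tr.n_tip = n_tip;
  tr.n_all = n_tip + (int)po_child.size() / 2;  // binary rooted: Nnode = Nedge/2
  tr.po_parent.assign(po_parent.begin(), po_parent.end());
  tr.po_child.assign(po_child.begin(), po_child.end());
  tr.po_len.assign(po_len.begin(), po_len.end());
  tr.sub_edges.resize(tr.n_all);
  tr.sub_tips.resize(tr.n_all);
  for (int b = 0; b < tr.n_all; ++b) {
    if (sub_edges[b] != R_NilValue) {
      IntegerVector se = sub_edges[b], stp = sub_tips[b];
      tr.sub_edges[b].assign(se.begin(), se.end());
      tr.sub_tips[b].assign(stp.begin(), stp.end());
    }
  }
  std::vector<double> x(traits.begin(), traits.end());
  double sd_x = 0.0, mean_x = 0.0;
  for (double v : x) mean_x += v;
  mean_x /= x.size();
  for (double v : x) sd_x += (v - mean_x) * (v - mean_x);
  sd_x = std::sqrt(sd_x / (x.size() - 1));
  if (sd_x <= 0) sd_x = 1.0;

  // branches eligible for shifts/jumps: every node except the root
  std::vector<int> branches;
  for (int b = 0; b < tr.n_all; ++b) if (b != n_tip) branches.push_back(b);
  const int NB = (int)branches.size();

  State st;
  st.sigma2 = sigma2_init; st.alpha = alpha_init;
  st.mult.assign(tr.n_all, 1.0);
  st.shift_m.assign(tr.n_all, 0.0);
  st.jump_s.assign(tr.n_all, 0.0);
  st.has_shift.assign(tr.n_all, false);
  st.has_jump.assign(tr.n_all, false);
  st.tip_offset.assign(n_tip, 0.0);
  st.loglik = prune_loglik(tr, x, st);

  const double w = prop_width / 8.0;  // calibration-relative width
  const int burnin = (int)std::floor(burnin_frac * ngen);
  const int n_samp = (ngen - burnin) / thin;
  NumericMatrix trace(n_samp, 6);
  colnames(trace) = CharacterVector::create("gen", "loglik", "sigma2",
                                            "alpha", "k_shifts", "k_jumps");
  std::vector<double> shift_hits(tr.n_all, 0.0), jump_hits(tr.n_all, 0.0);
  std::vector<double> jump_size_sum(tr.n_all, 0.0);
  long post_iters = 0; long n_acc = 0, n_prop = 0;
  int si = 0;

  for (int g = 1; g <= ngen; ++g) {
    // move menu
    double u = unif_rand();
    double ll_new;
    bool accepted = false;
    ++n_prop;
    double p_base = (allow_shifts || allow_jumps) ? 0.4 : 1.0;
    if (u < p_base * 0.6) {
      // sigma2 log random walk (prior 1/sigma2 cancels the Jacobian)
      double old = st.sigma2;
      double lp_old = allow_jumps ? jump_prior_logdens(st, jump_c, med_bl) : 0.0;
      st.sigma2 = old * std::exp((unif_rand() * 2 - 1) * 0.6 * w);
      ll_new = prune_loglik(tr, x, st);
      double lp_new = allow_jumps ? jump_prior_logdens(st, jump_c, med_bl) : 0.0;
      if (std::log(unif_rand()) < ll_new - st.loglik + lp_new - lp_old) {
        st.loglik = ll_new; accepted = true;
      } else st.sigma2 = old;
    } else if (u < p_base) {
      double old = st.alpha;
      st.alpha = old + (unif_rand() * 2 - 1) * 0.4 * w * sd_x;
      ll_new = prune_loglik(tr, x, st);
      if (std::log(unif_rand()) < ll_new - st.loglik) {
        st.loglik = ll_new; accepted = true;
      } else st.alpha = old;
    } else {
      // dimension / structure moves, split between jump and shift blocks
      bool do_jump;
      if (allow_jumps && allow_shifts) do_jump = unif_rand() < 0.5;
      else do_jump = allow_jumps;
      if (do_jump) {
        double v = unif_rand();
        double tau = std::sqrt(jump_tau2(st, jump_c, med_bl));
        if (v < 0.35) {               // birth
          if (st.k_jump < NB) {
            int b;
            do { b = pick_branch(branches); } while (st.has_jump[b]);
            double s = norm_rand() * tau;
            st.has_jump[b] = true; st.jump_s[b] = s; st.k_jump++;
            apply_jump_delta(tr, st, b, s);
            ll_new = prune_loglik(tr, x, st);
            double logA = ll_new - st.loglik +
              std::log(poisson_mean / st.k_jump);
            if (std::log(unif_rand()) < logA) { st.loglik = ll_new; accepted = true; }
            else {
              apply_jump_delta(tr, st, b, -s);
              st.has_jump[b] = false; st.jump_s[b] = 0.0; st.k_jump--;
            }
          }
        } else if (v < 0.7) {         // death
          if (st.k_jump > 0) {
            std::vector<int> cur;
            for (int b : branches) if (st.has_jump[b]) cur.push_back(b);
            int b = pick_branch(cur);
            double s = st.jump_s[b];
            apply_jump_delta(tr, st, b, -s);
            st.has_jump[b] = false; st.jump_s[b] = 0.0;
            ll_new = prune_loglik(tr, x, st);
            double logA = ll_new - st.loglik +
              std::log((double)st.k_jump / poisson_mean);
            if (std::log(unif_rand()) < logA) {
              st.k_jump--; st.loglik = ll_new; accepted = true;
            } else {
              st.has_jump[b] = true; st.jump_s[b] = s;
              apply_jump_delta(tr, st, b, s);
            }
          }
        } else if (v < 0.85) {        // relocate
          if (st.k_jump > 0 && st.k_jump < NB) {
            std::vector<int> cur;
            for (int b : branches) if (st.has_jump[b]) cur.push_back(b);
            int b = pick_branch(cur);
            int b2;
            do { b2 = pick_branch(branches); } while (st.has_jump[b2]);
            double s = st.jump_s[b];
            apply_jump_delta(tr, st, b, -s);
            apply_jump_delta(tr, st, b2, s);
            st.has_jump[b] = false; st.jump_s[b] = 0.0;
            st.has_jump[b2] = true; st.jump_s[b2] = s;
            ll_new = prune_loglik(tr, x, st);
            if (std::log(unif_rand()) < ll_new - st.loglik) {
              st.loglik = ll_new; accepted = true;
            } else {
              apply_jump_delta(tr, st, b2, -s);
              apply_jump_delta(tr, st, b, s);
              st.has_jump[b2] = false; st.jump_s[b2] = 0.0;
              st.has_jump[b] = true; st.jump_s[b] = s;
            }
          }
        } else {                      // resize
          if (st.k_jump > 0) {
            std::vector<int> cur;
            for (int b : branches) if (st.has_jump[b]) cur.push_back(b);
            int b = pick_branch(cur);
            double s = st.jump_s[b];
            double s2 = s + norm_rand() * 0.25 * w * sd_x;
            apply_jump_delta(tr, st, b, s2 - s);
            st.jump_s[b] = s2;
            ll_new = prune_loglik(tr, x, st);
            double logA = ll_new - st.loglik +
              (s * s - s2 * s2) / (2.0 * tau * tau);
            if (std::log(unif_rand()) < logA) { st.loglik = ll_new; accepted = true; }
            else {
              apply_jump_delta(tr, st, b, s - s2);
              st.jump_s[b] = s;
            }
          }
        }
      } else if (allow_shifts) {
        double v = unif_rand();
        if (v < 0.35) {               // birth
          if (st.k_shift < NB) {
            int b;
            do { b = pick_branch(branches); } while (st.has_shift[b]);
            double m = std::exp(norm_rand());  // lognormal(0,1) = prior
            st.has_shift[b] = true; st.shift_m[b] = m; st.k_shift++;
            apply_shift_factor(tr, st, b, m);
            ll_new = prune_loglik(tr, x, st);
            double logA = ll_new - st.loglik +
              std::log(poisson_mean / st.k_shift);
            if (std::log(unif_rand()) < logA) { st.loglik = ll_new; accepted = true; }
            else {
              apply_shift_factor(tr, st, b, 1.0 / m);
              st.has_shift[b] = false; st.shift_m[b] = 0.0; st.k_shift--;
            }
          }
        } else if (v < 0.7) {         // death
          if (st.k_shift > 0) {
            std::vector<int> cur;
            for (int b : branches) if (st.has_shift[b]) cur.push_back(b);
            int b = pick_branch(cur);
            double m = st.shift_m[b];
            apply_shift_factor(tr, st, b, 1.0 / m);
            st.has_shift[b] = false; st.shift_m[b] = 0.0;
            ll_new = prune_loglik(tr, x, st);
            double logA = ll_new - st.loglik +
              std::log((double)st.k_shift / poisson_mean);
            if (std::log(unif_rand()) < logA) {
              st.k_shift--; st.loglik = ll_new; accepted = true;
            } else {
              st.has_shift[b] = true; st.shift_m[b] = m;
              apply_shift_factor(tr, st, b, m);
            }
          }
        } else if (v < 0.85) {        // relocate
          if (st.k_shift > 0 && st.k_shift < NB) {
            std::vector<int> cur;
            for (int b : branches) if (st.has_shift[b]) cur.push_back(b);
            int b = pick_branch(cur);
            int b2;
            do { b2 = pick_branch(branches); } while (st.has_shift[b2]);
            double m = st.shift_m[b];
            apply_shift_factor(tr, st, b, 1.0 / m);
            apply_shift_factor(tr, st, b2, m);
            st.has_shift[b] = false; st.shift_m[b] = 0.0;
            st.has_shift[b2] = true; st.shift_m[b2] = m;
            ll_new = prune_loglik(tr, x, st);
            if (std::log(unif_rand()) < ll_new - st.loglik) {
              st.loglik = ll_new; accepted = true;
            } else {
              apply_shift_factor(tr, st, b2, 1.0 / m);
              apply_shift_factor(tr, st, b, m);
              st.has_shift[b2] = false; st.shift_m[b2] = 0.0;
              st.has_shift[b] = true; st.shift_m[b] = m;
            }
          }
        } else {                      // resize multiplier
          if (st.k_shift > 0) {
            std::vector<int> cur;
            for (int b : branches) if (st.has_shift[b]) cur.push_back(b);
            int b = pick_branch(cur);
            double m = st.shift_m[b];
            double m2 = m * std::exp(norm_rand() * 0.3 * w);
            apply_shift_factor(tr, st, b, m2 / m);
            st.shift_m[b] = m2;
            ll_new = prune_loglik(tr, x, st);
            double lm = std::log(m), lm2 = std::log(m2);
            double logA = ll_new - st.loglik + (lm * lm - lm2 * lm2) / 2.0;
            if (std::log(unif_rand()) < logA) { st.loglik = ll_new; accepted = true; }
            else {
              apply_shift_factor(tr, st, b, m / m2);
              st.shift_m[b] = m;
            }
          }
        }
      }
    }
    if (accepted) ++n_acc;

    // guard against multiplicative drift in cached quantities
    if (g % 50000 == 0) {
      std::fill(st.mult.begin(), st.mult.end(), 1.0);
      for (int b : branches) if (st.has_shift[b])
        apply_shift_factor(tr, st, b, st.shift_m[b]);
      std::fill(st.tip_offset.begin(), st.tip_offset.end(), 0.0);
      for (int b : branches) if (st.has_jump[b])
        apply_jump_delta(tr, st, b, st.jump_s[b]);
      st.loglik = prune_loglik(tr, x, st);
    }

    if (g > burnin) {
      ++post_iters;
      for (int b : branches) {
        if (st.has_shift[b]) shift_hits[b] += 1.0;
        if (st.has_jump[b]) { jump_hits[b] += 1.0; jump_size_sum[b] += st.jump_s[b]; }
      }
      if ((g - burnin) % thin == 0 && si < n_samp) {
        trace(si, 0) = g; trace(si, 1) = st.loglik; trace(si, 2) = st.sigma2;
        trace(si, 3) = st.alpha; trace(si, 4) = st.k_shift;
        trace(si, 5) = st.k_jump;
        ++si;
      }
    }
  }

  NumericVector shift_prob(tr.n_all), jump_prob(tr.n_all), jump_mean(tr.n_all);
  for (int b = 0; b < tr.n_all; ++b) {
    shift_prob[b] = post_iters ? shift_hits[b] / post_iters : 0.0;
    jump_prob[b] = post_iters ? jump_hits[b] / post_iters : 0.0;
    jump_mean[b] = jump_hits[b] > 0 ? jump_size_sum[b] / jump_hits[b] : NA_REAL;
  }
  return List::create(
    _["trace"] = trace, _["shift_prob"] = shift_prob,
    _["jump_prob"] = jump_prob, _["jump_mean_size"] = jump_mean,
    _["acceptance_rate"] = (double)n_acc / (double)n_prop);
}
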