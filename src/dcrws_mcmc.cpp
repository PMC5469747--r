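// Metropolis-within-Gibbs sampler for the two-state hierarchical
// switching first-difference correlated random walk (DCRWS) state-space
// model. Movement parameters (gamma, theta, alpha, Sigma) are pooled
// across segments; latent locations and behavioural states are sampled
// per segment. Observations are linearly interpolated to fix times and
// carry per-location-class Student-t errors.
//
// All randomness comes from R's RNG (RNGScope), so results are
// reproducible from set.seed() in R.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Obs {
  double yx, yy;   // observed lon, lat (degrees)
  int t;           // 0-based node index; position = (1-j)*x[t] + j*x[t+1]
  double j;        // fractional position in [0,1); j==0 when t==n-1
  double tau;      // t error scale (degrees, per coordinate)
  double nu;       // t degrees of freedom
  double lconst;   // per-coordinate log-density constant
};

struct Seg {
  int n;                       // number of regular nodes
  std::vector<double> xx, xy;  // latent locations
  std::vector<int> b;          // b[t] in {1,2} governs transition t->t+1,
                               // meaningful for t = 1..n-2 (0-based)
  std::vector<Obs> obs;
  std::vector<std::vector<int> > obs_at;  // obs indices touching node k
  std::vector<double> xscale;  // adaptive RW scale per node
  std::vector<int> xacc;       // acceptance counters (per adaptation batch)
};

struct Pars {
  double g[2];      // gamma_1 (transit), gamma_2 (ARS); g[0] > g[1]
  double th[2];     // mean turning angles
  double a[2];      // a[k-1] = P(b_t = 1 | b_{t-1} = k)
  double sx, sy, rho;
};

struct SigmaCache {
  double ixx, ixy, iyy, lconst;  // inverse entries and -log(2*pi)-0.5*logdet
  void update(double sx, double sy, double rho) {
    double det = sx * sx * sy * sy * (1.0 - rho * rho);
    ixx = sy * sy / det;
    iyy = sx * sx / det;
    ixy = -rho * sx * sy / det;
    lconst = -std::log(2.0 * M_PI) - 0.5 * std::log(det);
  }
};

inline double obs_ll(const Seg& s, const Obs& o) {
  double px, py;
  if (o.t >= s.n - 1) {
    px = s.xx[s.n - 1];
    py = s.xy[s.n - 1];
  } else {
    px = (1.0 - o.j) * s.xx[o.t] + o.j * s.xx[o.t + 1];
    py = (1.0 - o.j) * s.xy[o.t] + o.j * s.xy[o.t + 1];
  }
  double rx = (o.yx - px) / o.tau, ry = (o.yy - py) / o.tau;
  return 2.0 * o.lconst -
         0.5 * (o.nu + 1.0) *
             (std::log1p(rx * rx / o.nu) + std::log1p(ry * ry / o.nu));
}

// log-density of transition t -> t+1 (requires 1 <= t <= n-2) with an
// explicit behavioural state and parameters.
inline double trans_ll(const Seg& s, int t, int state, const Pars& p,
                       const SigmaCache& S) {
  double dxx = s.xx[t] - s.xx[t - 1], dxy = s.xy[t] - s.xy[t - 1];
  double g = p.g[state - 1], th = p.th[state - 1];
  double c = std::cos(th), sn = std::sin(th);
  double mx = s.xx[t] + g * (c * dxx - sn * dxy);
  double my = s.xy[t] + g * (sn * dxx + c * dxy);
  double ex = s.xx[t + 1] - mx, ey = s.xy[t + 1] - my;
  return S.lconst - 0.5 * (ex * ex * S.ixx + 2.0 * ex * ey * S.ixy +
                           ey * ey * S.iyy);
}

// Prior on the first difference, d_1 ~ N(0, Sigma): anchors the first
// node, which otherwise enters the likelihood only through gamma_b *
// d_1 and becomes unidentified when gamma is small.
inline double first_diff_ll(const Seg& s, const SigmaCache& S) {
  double ex = s.xx[1] - s.xx[0], ey = s.xy[1] - s.xy[0];
  return S.lconst - 0.5 * (ex * ex * S.ixx + 2.0 * ex * ey * S.ixy +
                           ey * ey * S.iyy);
}

inline double seg_state_ll(const std::vector<Seg>& segs, int state,
                           const Pars& p, const SigmaCache& S) {
  double ll = 0.0;
  for (size_t i = 0; i < segs.size(); ++i)
    for (int t = 1; t <= segs[i].n - 2; ++t)
      if (segs[i].b[t] == state) ll += trans_ll(segs[i], t, state, p, S);
  return ll;
}

inline double all_trans_ll(const std::vector<Seg>& segs, const Pars& p,
                           const SigmaCache& S) {
  double ll = 0.0;
  for (size_t i = 0; i < segs.size(); ++i) {
    ll += first_diff_ll(segs[i], S);
    for (int t = 1; t <= segs[i].n - 2; ++t)
      ll += trans_ll(segs[i], t, segs[i].b[t], p, S);
  }
  return ll;
}

inline double runif1() { return R::runif(0.0, 1.0); }

// Fold a random-walk proposal back into (lo, hi); keeps the proposal
// kernel symmetric so no Hastings correction is needed, and avoids
// boundary trapping of the adaptive scales.
inline double reflect(double x, double lo, double hi) {
  double w = hi - lo;
  if (w <= 0) return lo;
  double y = x - lo;
  y -= 2.0 * w * std::floor(y / (2.0 * w));
  return lo + (y <= w ? y : 2.0 * w - y);
}

}  // namespace

// [[Rcpp::export]]
List dcrws_mcmc_chain(List seg_list, NumericVector init_params, List prior,
                      int n_burn, int n_post, int thin) {
  const int nseg = seg_list.size();
  std::vector<Seg> segs(nseg);
  for (int i = 0; i < nseg; ++i) {
    List sl = seg_list[i];
    Seg& s = segs[i];
    s.n = as<int>(sl["n"]);
    NumericMatrix x0 = sl["x0"];
    s.xx.assign(s.n, 0.0);
    s.xy.assign(s.n, 0.0);
    for (int t = 0; t < s.n; ++t) {
      s.xx[t] = x0(t, 0);
      s.xy[t] = x0(t, 1);
    }
    s.b.assign(s.n, 1);
    NumericMatrix y = sl["y"];
    IntegerVector oidx = sl["oidx"];
    NumericVector oj = sl["oj"], otau = sl["otau"], onu = sl["onu"];
    int m = y.nrow();
    s.obs.resize(m);
    s.obs_at.assign(s.n, std::vector<int>());
    for (int k = 0; k < m; ++k) {
      Obs& o = s.obs[k];
      o.yx = y(k, 0);
      o.yy = y(k, 1);
      o.t = oidx[k];
      o.j = oj[k];
      o.tau = otau[k];
      o.nu = onu[k];
      o.lconst = R::lgammafn((o.nu + 1.0) / 2.0) - R::lgammafn(o.nu / 2.0) -
                 0.5 * std::log(o.nu * M_PI) - std::log(o.tau);
      if (o.t <= s.n - 1) s.obs_at[o.t].push_back(k);
      if (o.j > 0.0 && o.t + 1 <= s.n - 1) s.obs_at[o.t + 1].push_back(k);
    }
    s.xscale.assign(s.n, 0.05);
    s.xacc.assign(s.n, 0);
  }

  Pars p;
  p.g[0] = init_params[0];
  p.g[1] = init_params[1];
  p.th[0] = init_params[2];
  p.th[1] = init_params[3];
  p.a[0] = init_params[4];
  p.a[1] = init_params[5];
  p.sx = init_params[6];
  p.sy = init_params[7];
  p.rho = init_params[8];
  SigmaCache S;
  S.update(p.sx, p.sy, p.rho);

  const double sigma0 = as<double>(prior["sigma0"]);
  const double th1max = as<double>(prior["theta1_max"]);
  NumericVector g1s = prior["gamma1_shape"], g2s = prior["gamma2_shape"];
  const double ga[2] = {g1s[0], g2s[0]}, gb[2] = {g1s[1], g2s[1]};
  // log Beta(a,b) prior kernel for gamma (normalising constant drops)
  auto lgprior = [&](int k, double g) {
    return (ga[k] - 1.0) * std::log(g) + (gb[k] - 1.0) * std::log1p(-g);
  };

  // adaptive scales for the parameter blocks
  double sc_g[2] = {0.05, 0.05}, sc_th[2] = {0.2, 0.4}, sc_sig = 0.05;
  double sc_ab[2] = {0.05, 0.05};
  int acc_g[2] = {0, 0}, acc_th[2] = {0, 0}, acc_sig = 0;
  int acc_ab[2] = {0, 0};
  const int batch = 50;

  const int n_iter = n_burn + n_post;
  const int n_keep = n_post / thin;
  NumericMatrix out_par(n_keep, 9);
  std::vector<IntegerMatrix> out_b;
  std::vector<NumericMatrix> out_x;
  for (int i = 0; i < nseg; ++i) {
    out_b.push_back(IntegerMatrix(n_keep, segs[i].n));
    out_x.push_back(NumericMatrix(n_keep, 2 * segs[i].n));
  }
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- 1. Gibbs update of behavioural states -----------------------
    for (int i = 0; i < nseg; ++i) {
      Seg& s = segs[i];
      for (int t = 1; t <= s.n - 2; ++t) {
        double lw[2];
        for (int k = 1; k <= 2; ++k) {
          double lp = trans_ll(s, t, k, p, S);
          if (t > 1) {
            int prev = s.b[t - 1];
            double pr1 = p.a[prev - 1];
            lp += std::log(k == 1 ? pr1 : 1.0 - pr1);
          } else {
            lp += std::log(0.5);  // uniform prior on the initial state
          }
          if (t < s.n - 2) {
            int nxt = s.b[t + 1];
            double pr1 = p.a[k - 1];
            lp += std::log(nxt == 1 ? pr1 : 1.0 - pr1);
          }
          lw[k - 1] = lp;
        }
        double mx = std::max(lw[0], lw[1]);
        double w1 = std::exp(lw[0] - mx), w2 = std::exp(lw[1] - mx);
        s.b[t] = (runif1() < w1 / (w1 + w2)) ? 1 : 2;
      }
    }

    // --- 2. Metropolis update of latent locations --------------------
    for (int i = 0; i < nseg; ++i) {
      Seg& s = segs[i];
      for (int t = 0; t < s.n; ++t) {
        double oxx = s.xx[t], oxy = s.xy[t];
        double ll0 = 0.0, ll1 = 0.0;
        int tlo = std::max(1, t - 1), thi = std::min(s.n - 2, t + 1);
        for (int tt = tlo; tt <= thi; ++tt)
          ll0 += trans_ll(s, tt, s.b[tt], p, S);
        if (t <= 1) ll0 += first_diff_ll(s, S);
        for (size_t q = 0; q < s.obs_at[t].size(); ++q)
          ll0 += obs_ll(s, s.obs[s.obs_at[t][q]]);
        s.xx[t] = oxx + s.xscale[t] * R::norm_rand();
        s.xy[t] = oxy + s.xscale[t] * R::norm_rand();
        for (int tt = tlo; tt <= thi; ++tt)
          ll1 += trans_ll(s, tt, s.b[tt], p, S);
        if (t <= 1) ll1 += first_diff_ll(s, S);
        for (size_t q = 0; q < s.obs_at[t].size(); ++q)
          ll1 += obs_ll(s, s.obs[s.obs_at[t][q]]);
        if (std::log(runif1()) < ll1 - ll0) {
          s.xacc[t]++;
        } else {
          s.xx[t] = oxx;
          s.xy[t] = oxy;
        }
      }
    }

    // --- 3. gamma (uniform priors truncated to gamma1 > gamma2) ------
    for (int k = 0; k < 2; ++k) {
      double lo = (k == 0) ? p.g[1] : 0.0;
      double hi = (k == 0) ? 1.0 : p.g[0];
      double cand = reflect(p.g[k] + sc_g[k] * R::norm_rand(), lo, hi);
      Pars pc = p;
      pc.g[k] = cand;
      double d = seg_state_ll(segs, k + 1, pc, S) -
                 seg_state_ll(segs, k + 1, p, S) +
                 lgprior(k, cand) - lgprior(k, p.g[k]);
      if (std::log(runif1()) < d) {
        p.g[k] = cand;
        acc_g[k]++;
      }
    }

    // --- 4. theta ----------------------------------------------------
    {
      double cand = reflect(p.th[0] + sc_th[0] * R::norm_rand(),
                            -th1max, th1max);
      {
        Pars pc = p;
        pc.th[0] = cand;
        double d = seg_state_ll(segs, 1, pc, S) - seg_state_ll(segs, 1, p, S);
        if (std::log(runif1()) < d) {
          p.th[0] = cand;
          acc_th[0]++;
        }
      }
      cand = p.th[1] + sc_th[1] * R::norm_rand();
      while (cand > M_PI) cand -= 2.0 * M_PI;   // wrap into (-pi, pi]
      while (cand <= -M_PI) cand += 2.0 * M_PI;
      Pars pc = p;
      pc.th[1] = cand;
      double d = seg_state_ll(segs, 2, pc, S) - seg_state_ll(segs, 2, p, S);
      if (std::log(runif1()) < d) {
        p.th[1] = cand;
        acc_th[1]++;
      }
    }

    // --- 4b. joint (gamma, theta) update in Cartesian coordinates ----
    // The matrix gamma*T(theta) depends on (a, b) = gamma*(cos, sin)
    // theta; a random walk in (a, b) moves through the origin, so the
    // turning angle can flip even when gamma is small (the polar
    // parameterisation is degenerate at gamma = 0). The uniform
    // (gamma, theta) prior contributes a 1/gamma Jacobian.
    for (int k = 0; k < 2; ++k) {
      double a = p.g[k] * std::cos(p.th[k]);
      double b = p.g[k] * std::sin(p.th[k]);
      double ca = a + sc_ab[k] * R::norm_rand();
      double cb = b + sc_ab[k] * R::norm_rand();
      double r = std::sqrt(ca * ca + cb * cb);
      double th = std::atan2(cb, ca);
      bool ok = r > 1e-8 && r < 1.0;
      if (k == 0) ok = ok && r > p.g[1] && std::fabs(th) < th1max;
      else ok = ok && r < p.g[0];
      if (ok) {
        Pars pc = p;
        pc.g[k] = r;
        pc.th[k] = th;
        double d = seg_state_ll(segs, k + 1, pc, S) -
                   seg_state_ll(segs, k + 1, p, S) +
                   std::log(p.g[k]) - std::log(r) +
                   lgprior(k, r) - lgprior(k, p.g[k]);
        if (std::log(runif1()) < d) {
          p.g[k] = r;
          p.th[k] = th;
          acc_ab[k]++;
        }
      }
    }

    // --- 5. Sigma block (half-normal scales, uniform correlation) ----
    {
      double csx = p.sx + sc_sig * R::norm_rand();
      double csy = p.sy + sc_sig * R::norm_rand();
      double crho = p.rho + 0.5 * sc_sig * R::norm_rand();
      if (csx > 1e-6 && csy > 1e-6 && std::fabs(crho) < 0.999) {
        SigmaCache Sc;
        Sc.update(csx, csy, crho);
        double d = all_trans_ll(segs, p, Sc) - all_trans_ll(segs, p, S);
        d += -(csx * csx + csy * csy) / (2.0 * sigma0 * sigma0) +
             (p.sx * p.sx + p.sy * p.sy) / (2.0 * sigma0 * sigma0);
        if (std::log(runif1()) < d) {
          p.sx = csx;
          p.sy = csy;
          p.rho = crho;
          S = Sc;
        acc_sig++;
        }
      }
    }

    // --- 6. alpha (conjugate Beta full conditionals) -----------------
    {
      int n11 = 0, n12 = 0, n21 = 0, n22 = 0;
      for (int i = 0; i < nseg; ++i) {
        const Seg& s = segs[i];
        for (int t = 1; t <= s.n - 3; ++t) {
          if (s.b[t] == 1) {
            if (s.b[t + 1] == 1) n11++; else n12++;
          } else {
            if (s.b[t + 1] == 1) n21++; else n22++;
          }
        }
      }
      p.a[0] = R::rbeta(1.0 + n11, 1.0 + n12);
      p.a[1] = R::rbeta(1.0 + n21, 1.0 + n22);
    }

    // --- adaptation during burn-in -----------------------------------
    if (iter <= n_burn && iter % batch == 0) {
      for (int i = 0; i < nseg; ++i) {
        Seg& s = segs[i];
        for (int t = 0; t < s.n; ++t) {
          double r = s.xacc[t] / double(batch);
          s.xscale[t] *= (r > 0.3) ? 1.15 : (1.0 / 1.15);
          s.xscale[t] = std::min(std::max(s.xscale[t], 1e-4), 5.0);
          s.xacc[t] = 0;
        }
      }
      for (int k = 0; k < 2; ++k) {
        sc_g[k] *= (acc_g[k] / double(batch) > 0.3) ? 1.15 : (1.0 / 1.15);
        sc_g[k] = std::min(std::max(sc_g[k], 1e-4), 1.0);
        acc_g[k] = 0;
        sc_th[k] *= (acc_th[k] / double(batch) > 0.3) ? 1.15 : (1.0 / 1.15);
        sc_th[k] = std::min(std::max(sc_th[k], 1e-3), 3.0);
        acc_th[k] = 0;
        sc_ab[k] *= (acc_ab[k] / double(batch) > 0.3) ? 1.15 : (1.0 / 1.15);
        sc_ab[k] = std::min(std::max(sc_ab[k], 1e-3), 1.0);
        acc_ab[k] = 0;
      }
      sc_sig *= (acc_sig / double(batch) > 0.3) ? 1.15 : (1.0 / 1.15);
      sc_sig = std::min(std::max(sc_sig, 1e-5), 1.0);
      acc_sig = 0;
    }

    // --- record -------------------------------------------------------
    if (iter > n_burn && (iter - n_burn) % thin == 0 && kept < n_keep) {
      out_par(kept, 0) = p.g[0];
      out_par(kept, 1) = p.g[1];
      out_par(kept, 2) = p.th[0];
      out_par(kept, 3) = p.th[1];
      out_par(kept, 4) = p.a[0];
      out_par(kept, 5) = p.a[1];
      out_par(kept, 6) = p.sx;
      out_par(kept, 7) = p.sy;
      out_par(kept, 8) = p.rho;
      for (int i = 0; i < nseg; ++i) {
        Seg& s = segs[i];
        for (int t = 0; t < s.n; ++t) {
          int bt = s.b[t];
          if (t == 0) bt = s.b[1];
          if (t == s.n - 1) bt = s.b[s.n - 2];
          out_b[i](kept, t) = bt;
          out_x[i](kept, t) = s.xx[t];
          out_x[i](kept, s.n + t) = s.xy[t];
        }
      }
      kept++;
    }
  }

  List bl(nseg), xl(nseg);
  for (int i = 0; i < nseg; ++i) {
    bl[i] = out_b[i];
    xl[i] = out_x[i];
  }
  colnames(out_par) = CharacterVector::create(
      "gamma1", "gamma2", "theta1", "theta2", "alpha1", "alpha2",
      "sigma_lon", "sigma_lat", "rho");
  return List::create(_["params"] = out_par, _["b"] = bl, _["x"] = xl);
}
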