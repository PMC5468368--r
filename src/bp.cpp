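// Belief-propagation core for the sparse stochastic block model.
//
// Messages live on directed edges: row m (0-based) of `cav` is the cavity
// bias psi^{src[m] -> dst[m]}; the reverse message of m is m + L (m < L) or
// m - L. Updates are asynchronous and vertex-blocked: vertices are visited
// in a seeded random order and all outgoing messages of a vertex are
// refreshed together, which allows the product-over-neighbours to be formed
// once per vertex (O(d q^2) per vertex, O(L q^2) per sweep).
//
// The non-edge field h_sigma = sum_k theta_k sum_{s} psi^k_s omega_{s sigma}
// is maintained incrementally as marginals change; vertex i feels
// exp(-theta_i * h_sigma). For the standard model theta is all ones.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double MSG_FLOOR = 1e-12;

// [[Rcpp::export]]
List bp_run_cpp(int n, int q,
                IntegerVector src, IntegerVector dst,      // length 2L, 1-based
                IntegerVector in_msg, IntegerVector in_ptr, // CSR by dst
                NumericVector gamma, NumericMatrix omega,
                NumericVector theta,
                NumericMatrix cav_in,                       // 2L x q
                double damping, double tol, int max_iter) {
  const int M = src.size();           // 2L directed messages
  // flat row-major copies for cache-friendly access in the hot loops
  std::vector<double> msg((size_t)M * q), mg((size_t)n * q, 0.0),
      om((size_t)q * q), hv(q, 0.0);
  for (int m = 0; m < M; ++m)
    for (int sig = 0; sig < q; ++sig) msg[(size_t)m * q + sig] = cav_in(m, sig);
  for (int a = 0; a < q; ++a)
    for (int b = 0; b < q; ++b) om[(size_t)a * q + b] = omega(a, b);
  NumericVector logZi(n);
  std::vector<double> s;              // per-vertex scratch: d x q incoming sums
  std::vector<double> P(q), u(q), upd(q), pri(q);
  std::vector<int> order(n);
  int resets = 0;

  RNGScope scope;

  // ---- helper lambdas -----------------------------------------------------
  auto incoming_count = [&](int i) { return in_ptr[i + 1] - in_ptr[i]; };

  // compute incoming sums s_m[sig] = sum_sk msg[m, sk] * omega[sk, sig]
  auto fill_sums = [&](int i) {
    int d = incoming_count(i);
    s.assign((size_t)d * q, 0.0);
    for (int a = 0; a < d; ++a) {
      int m = in_msg[in_ptr[i] + a] - 1;
      const double *mrow = &msg[(size_t)m * q];
      double *srow = &s[(size_t)a * q];
      for (int sk = 0; sk < q; ++sk) {
        double w = mrow[sk];
        const double *orow = &om[(size_t)sk * q];
        for (int sig = 0; sig < q; ++sig) srow[sig] += w * orow[sig];
      }
    }
    return d;
  };

  // prior factor gamma * exp(-theta_i h); field_on toggles the h term
  auto fill_prior = [&](int i, bool field_on) {
    double ti = theta[i];
    for (int sig = 0; sig < q; ++sig)
      pri[sig] = gamma[sig] * (field_on ? std::exp(-ti * hv[sig]) : 1.0);
  };

  // unnormalized marginal u = pri * prod_a s_a, rescaled; returns logZ_i
  auto vertex_product = [&](int i, int d) {
    double logscale = 0.0;
    for (int sig = 0; sig < q; ++sig) P[sig] = 1.0;
    for (int a = 0; a < d; ++a) {
      double mx = 0.0;
      for (int sig = 0; sig < q; ++sig)
        mx = std::max(mx, s[(size_t)a * q + sig]);
      if (mx <= 0.0) { // degenerate incoming sum; skip factor
        continue;
      }
      for (int sig = 0; sig < q; ++sig)
        P[sig] *= s[(size_t)a * q + sig] / mx;
      logscale += std::log(mx);
    }
    double Z = 0.0;
    for (int sig = 0; sig < q; ++sig) { u[sig] = pri[sig] * P[sig]; Z += u[sig]; }
    return std::log(Z) + logscale;
  };

  auto set_marginal_update_field = [&](int i) {
    double Z = 0.0;
    for (int sig = 0; sig < q; ++sig) Z += u[sig];
    if (Z <= 0.0) { for (int sig = 0; sig < q; ++sig) u[sig] = 1.0; Z = q; ++resets; }
    double ti = theta[i];
    double *mrow = &mg[(size_t)i * q];
    for (int sig = 0; sig < q; ++sig) {
      double newm = u[sig] / Z;
      double delta = ti * (newm - mrow[sig]);
      if (delta != 0.0) {
        const double *orow = &om[(size_t)sig * q];
        for (int s2 = 0; s2 < q; ++s2) hv[s2] += delta * orow[s2];
      }
      mrow[sig] = newm;
    }
  };

  // ---- initial marginals and field ---------------------------------------
  // two passes: field-free marginals, then field from them, then consistent
  // marginals under that field
  for (int pass = 0; pass < 2; ++pass) {
    for (int i = 0; i < n; ++i) {
      int d = fill_sums(i);
      fill_prior(i, pass == 1);
      logZi[i] = vertex_product(i, d);
      set_marginal_update_field(i);
    }
  }

  // ---- sweeps -------------------------------------------------------------
  int iter = 0;
  double max_change = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    max_change = 0.0;
    // seeded random vertex order (Fisher-Yates on R's RNG)
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int d = fill_sums(i);
      if (d == 0) {                  // isolated vertex: field-only marginal
        fill_prior(i, true);
        for (int sig = 0; sig < q; ++sig) u[sig] = pri[sig];
        double Z = 0.0;
        for (int sig = 0; sig < q; ++sig) Z += u[sig];
        logZi[i] = std::log(Z);
        set_marginal_update_field(i);
        continue;
      }
      fill_prior(i, true);
      logZi[i] = vertex_product(i, d);
      // outgoing messages: divide the full product by each incoming sum
      for (int a = 0; a < d; ++a) {
        int m = in_msg[in_ptr[i] + a] - 1;     // incoming k -> i
        int rev = (m < M / 2) ? m + M / 2 : m - M / 2;  // outgoing i -> k
        double mn = R_PosInf, mx = 0.0;
        for (int sig = 0; sig < q; ++sig) {
          double v = s[(size_t)a * q + sig];
          mn = std::min(mn, v); mx = std::max(mx, v);
        }
        if (mx <= 0.0 || mn < 1e-12 * mx) {
          // near-degenerate divisor: recompute the exclusion product directly
          for (int sig = 0; sig < q; ++sig) upd[sig] = pri[sig];
          for (int b = 0; b < d; ++b) {
            if (b == a) continue;
            double bmx = 0.0;
            for (int sig = 0; sig < q; ++sig)
              bmx = std::max(bmx, s[(size_t)b * q + sig]);
            if (bmx <= 0.0) continue;
            for (int sig = 0; sig < q; ++sig)
              upd[sig] *= s[(size_t)b * q + sig] / bmx;
          }
        } else {
          for (int sig = 0; sig < q; ++sig)
            upd[sig] = u[sig] / s[(size_t)a * q + sig];
        }
        double Z = 0.0;
        for (int sig = 0; sig < q; ++sig) Z += upd[sig];
        if (Z <= 0.0 || !std::isfinite(Z)) {
          for (int sig = 0; sig < q; ++sig) upd[sig] = 1.0 / q;
          ++resets;
        } else {
          for (int sig = 0; sig < q; ++sig) upd[sig] /= Z;
        }
        // floor then renormalize
        Z = 0.0;
        for (int sig = 0; sig < q; ++sig) {
          if (upd[sig] < MSG_FLOOR) upd[sig] = MSG_FLOOR;
          Z += upd[sig];
        }
        double *rrow = &msg[(size_t)rev * q];
        for (int sig = 0; sig < q; ++sig) {
          double newv = (1.0 - damping) * (upd[sig] / Z) + damping * rrow[sig];
          double ch = std::fabs(newv - rrow[sig]);
          if (ch > max_change) max_change = ch;
          rrow[sig] = newv;
        }
      }
      set_marginal_update_field(i);
    }
    if (max_change < tol) { ++iter; break; }
  }

  // ---- final consistent marginals / normalizers ---------------------------
  for (int i = 0; i < n; ++i) {
    int d = fill_sums(i);
    fill_prior(i, true);
    logZi[i] = vertex_product(i, d);
    set_marginal_update_field(i);
  }

  NumericMatrix cav_out(M, q), marg_out(n, q);
  for (int m = 0; m < M; ++m)
    for (int sig = 0; sig < q; ++sig) cav_out(m, sig) = msg[(size_t)m * q + sig];
  for (int i = 0; i < n; ++i)
    for (int sig = 0; sig < q; ++sig) marg_out(i, sig) = mg[(size_t)i * q + sig];
  NumericVector h_out(q);
  for (int sig = 0; sig < q; ++sig) h_out[sig] = hv[sig];
  return List::create(_["cav"] = cav_out, _["marginal"] = marg_out,
                      _["h"] = h_out, _["logZi"] = logZi,
                      _["iterations"] = iter,
                      _["max_change"] = max_change, _["resets"] = resets);
}
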