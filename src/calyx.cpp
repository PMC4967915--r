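#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler--Maruyama integrator on a tabulated 1-D force field.
//
// The landscape force -dU/dxi is supplied on a uniform grid (grid_min,
// grid_h) and interpolated linearly; the harmonic bias is evaluated
// analytically so a moving spring never suffers tabulation lag.  All
// random numbers come from R's RNG so set.seed() controls the trajectory.
//
// bias_kind: 0 = none, 1 = umbrella (fixed centre), 2 = moving spring
// Records xi every `sample_every` steps (after the update); for biased
// runs also records the instantaneous spring force k*(c - xi) in
// kJ/mol/nm and tracks its maximum over *all* steps.
// [[Rcpp::export]]
List langevin_cpp(double xi0, double n_steps_d, double dt, double mob,
                  double noise, double grid_min, double grid_h,
                  NumericVector force_tab, int bias_kind, double bias_k,
                  double bias_c0, double bias_v, int sample_every,
                  double lo, double hi) {
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  const R_xlen_t n_tab = force_tab.size();
  const R_xlen_t n_rec = n_steps / sample_every;
  NumericVector xi_rec(n_rec), f_rec(bias_kind == 0 ? 0 : n_rec);
  double xi = xi0, f_max = 0.0, t_f_max = 0.0;
  R_xlen_t irec = 0;
  RNGScope scope;

  for (R_xlen_t s = 0; s < n_steps; ++s) {
    // landscape force, linear interpolation with clamped ends
    double u = (xi - grid_min) / grid_h;
    R_xlen_t i0 = (R_xlen_t)std::floor(u);
    double fl;
    if (i0 < 0) fl = force_tab[0];
    else if (i0 >= n_tab - 1) fl = force_tab[n_tab - 1];
    else {
      double w = u - i0;
      fl = (1.0 - w) * force_tab[i0] + w * force_tab[i0 + 1];
    }
    double fb = 0.0;
    if (bias_kind == 1) fb = bias_k * (bias_c0 - xi);
    else if (bias_kind == 2) fb = bias_k * (bias_c0 + bias_v * (s * dt) - xi);

    xi += mob * (fl + fb) + noise * norm_rand();
    if (xi < lo) xi = 2.0 * lo - xi;
    if (xi > hi) xi = 2.0 * hi - xi;
    // a second clip guards pathological oversteps
    if (xi < lo) xi = lo;
    if (xi > hi) xi = hi;

    if (bias_kind != 0) {
      double c_now = (bias_kind == 1) ? bias_c0 : bias_c0 + bias_v * ((s + 1) * dt);
      double f_now = bias_k * (c_now - xi);
      if (f_now > f_max) { f_max = f_now; t_f_max = (s + 1) * dt; }
      if ((s + 1) % sample_every == 0 && irec < n_rec) f_rec[irec] = f_now;
    }
    if ((s + 1) % sample_every == 0 && irec < n_rec) xi_rec[irec++] = xi;
  }
  return List::create(_["xi"] = xi_rec, _["f_bias"] = f_rec,
                      _["f_max"] = f_max, _["t_f_max"] = t_f_max);
}

// Self-consistent WHAM iteration.
//
// H:  n_windows x n_bins histogram counts
// B:  n_windows x n_bins Boltzmann factors exp(-w_i(xi_b)/kT)
// N:  samples per window, wmult: window multiplicities (bootstrap weights)
// f0: starting free-energy constants (warm start for bootstrap replicates)
// Iterates P_b = C_b / sum_i m_i N_i exp(f_i/kT) B_ib,
//          f_i = -kT log sum_b P_b B_ib      (gauge: f_1 = 0)
// until max |delta f_i| < tol over windows with m_i > 0.
// [[Rcpp::export]]
List wham_cpp(NumericMatrix H, NumericMatrix B, NumericVector N,
              NumericVector wmult, double kT, double tol,
              double max_iter_d, NumericVector f0) {
  const int nw = H.nrow(), nb = H.ncol();
  const R_xlen_t max_iter = (R_xlen_t)max_iter_d;
  NumericVector f = clone(f0), fnew(nw), P(nb), Cb(nb);
  for (int b = 0; b < nb; ++b) {
    double c = 0.0;
    for (int i = 0; i < nw; ++i) c += wmult[i] * H(i, b);
    Cb[b] = c;
  }
  bool converged = false;
  R_xlen_t it = 0;
  for (it = 1; it <= max_iter; ++it) {
    for (int b = 0; b < nb; ++b) {
      if (Cb[b] <= 0.0) { P[b] = 0.0; continue; }
      double denom = 0.0;
      for (int i = 0; i < nw; ++i) {
        if (wmult[i] <= 0.0) continue;
        denom += wmult[i] * N[i] * std::exp(f[i] / kT) * B(i, b);
      }
      P[b] = Cb[b] / denom;
    }
    double s = 0.0;
    for (int b = 0; b < nb; ++b) s += P[b];
    for (int b = 0; b < nb; ++b) P[b] /= s;

    double delta = 0.0;
    for (int i = 0; i < nw; ++i) {
      double z = 0.0;
      for (int b = 0; b < nb; ++b) z += P[b] * B(i, b);
      fnew[i] = -kT * std::log(z);
    }
    double shift = fnew[0];
    for (int i = 0; i < nw; ++i) {
      fnew[i] -= shift;
      if (wmult[i] > 0.0) {
        double d = std::fabs(fnew[i] - f[i]);
        if (d > delta) delta = d;
      }
      f[i] = fnew[i];
    }
    if (delta < tol) { converged = true; break; }
  }
  return List::create(_["f"] = f, _["P"] = P,
                      _["n_iterations"] = (double)(converged ? it : max_iter),
                      _["converged"] = converged);
}
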