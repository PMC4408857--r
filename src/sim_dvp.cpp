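#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled stochastic Duffing-van der Pol
// pair.  State is (x1, v1, x2, v2); the Wiener increment enters only the
// second oscillator's velocity, scaled by mu * sqrt(h).
//
// par: (k1, k2, b1, b2, eps1, eps2, mu)
// h: internal step (s); n_steps: internal steps; thin: keep every thin-th step
// noise: optional pre-generated standard-normal increments (length n_steps);
//        when empty, draws from R's RNG so seeding via set.seed() applies.
//
// Returns a list with blowup flag (and the 1-based offending step), the
// thinned state matrix, and the final full state.
// [[Rcpp::export(name = ".sim_dvp_cpp")]]
List sim_dvp_cpp(NumericVector par, double h, int n_steps, int thin,
                 NumericVector state0, NumericVector noise) {
  double k1 = par[0], k2 = par[1], b1 = par[2], b2 = par[3];
  double e1 = par[4], e2 = par[5], mu = par[6];
  double x1 = state0[0], v1 = state0[1], x2 = state0[2], v2 = state0[3];
  const bool use_noise = noise.size() > 0;
  const double sqh = std::sqrt(h);
  const int n_out = n_steps / thin;
  NumericMatrix out(n_out, 4);
  int j = 0;
  for (int i = 0; i < n_steps; ++i) {
    const double d = x1 - x2;
    const double d3 = d * d * d;
    const double a1 = -(k1 + k2) * x1 + k2 * x2 - b1 * x1 * x1 * x1 - b2 * d3 +
                      e1 * v1 * (1.0 - x1 * x1);
    const double a2 = k2 * x1 - k2 * x2 + b2 * d3 + e2 * v2 * (1.0 - x2 * x2);
    const double z = use_noise ? noise[i] : norm_rand();
    x1 += h * v1;
    x2 += h * v2;
    v1 += h * a1;
    v2 += h * a2 + mu * sqh * z;
    if (!(R_finite(x1) && R_finite(v1) && R_finite(x2) && R_finite(v2))) {
      return List::create(_["blowup"] = true, _["step"] = i + 1);
    }
    if ((i + 1) % thin == 0) {
      out(j, 0) = x1;
      out(j, 1) = v1;
      out(j, 2) = x2;
      out(j, 3) = v2;
      ++j;
    }
  }
  return List::create(_["blowup"] = false, _["states"] = out,
                      _["final"] = NumericVector::create(x1, v1, x2, v2));
}
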