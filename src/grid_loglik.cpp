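#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bernoulli choice log-likelihood over a full parameter grid for the
// two-stream softmax models: p(choose A) = 1 / (1 + exp(-(bw*rw - bl*rl))).
//
// Rw: T x Ka win-belief trajectories (column i computed under alpha_win[i])
// Rl: T x Kb loss-belief trajectories
// bw: Ku win inverse temperatures; bl: Kl loss inverse temperatures
// choiceA: per-trial 0/1 (1 = chose A); include: trials entering the sum
// tie_betas: single shared temperature (bl ignored; result has no bl dim)
//
// Returns an array of dim (Ka, Kb, Ku) or (Ka, Kb, Ku, Kl).
//
// The inner loop is kept free of transcendental calls by writing
// exp(-(bw*rw - bl*rl)) = exp(-bw*rw) * exp(bl*rl), tabulating the two
// factors per trial, and accumulating the likelihood as a running product
// whose log is harvested every CHUNK trials (probabilities are floored at
// 1e-12, so a 12-trial product stays far above double underflow).
// [[Rcpp::export]]
NumericVector grid_loglik_cpp(NumericMatrix Rw, NumericMatrix Rl,
                              NumericVector bw, NumericVector bl,
                              IntegerVector choiceA, LogicalVector include,
                              bool tie_betas) {
  const int T = Rw.nrow();
  const int Ka = Rw.ncol(), Kb = Rl.ncol();
  const int Ku = bw.size();
  const int Kl = tie_betas ? 1 : bl.size();
  if (Rl.nrow() != T || choiceA.size() != T || include.size() != T)
    stop("trial dimensions do not align");

  const int CHUNK = 12;
  const R_xlen_t N = (R_xlen_t)Ka * Kb * Ku * Kl;

  NumericVector ll(N);
  // p(choice) = [m if B else 1] / (1 + m) with m = exp(-x); accumulate
  // numerator and denominator products separately so the inner loop needs
  // no division or log. Clamping m to [1e-12, 1e12] floors the choice
  // probability near 1e-12 and, with 12-trial chunks, keeps both products
  // far inside double range (1e12^12 = 1e144).
  std::vector<double> accn(N, 1.0), accd(N, 1.0);
  std::vector<double> P1((size_t)Ka * Ku);        // exp(-bw_u * rw_i)
  std::vector<double> P2((size_t)Kb * (tie_betas ? Ku : Kl)); // exp(b * rl_j)

  int in_chunk = 0;
  for (int t = 0; t < T; ++t) {
    if (!include[t]) continue;
    for (int u = 0; u < Ku; ++u)
      for (int i = 0; i < Ka; ++i)
        P1[(size_t)u * Ka + i] = std::exp(-bw[u] * Rw(t, i));
    if (tie_betas) {
      for (int u = 0; u < Ku; ++u)
        for (int j = 0; j < Kb; ++j)
          P2[(size_t)u * Kb + j] = std::exp(bw[u] * Rl(t, j));
    } else {
      for (int l = 0; l < Kl; ++l)
        for (int j = 0; j < Kb; ++j)
          P2[(size_t)l * Kb + j] = std::exp(bl[l] * Rl(t, j));
    }
    const bool choseA = choiceA[t] == 1;
    R_xlen_t idx = 0;
    for (int l = 0; l < Kl; ++l) {
      for (int u = 0; u < Ku; ++u) {
        const double *p2 = &P2[(size_t)(tie_betas ? u : l) * Kb];
        const double *p1 = &P1[(size_t)u * Ka];
        if (choseA) {
          for (int j = 0; j < Kb; ++j) {
            const double m2 = p2[j];
            for (int i = 0; i < Ka; ++i, ++idx) {
              double m = p1[i] * m2;   // exp(-x)
              m = m < 1e-12 ? 1e-12 : (m > 1e12 ? 1e12 : m);
              accd[idx] *= 1.0 + m;
            }
          }
        } else {
          for (int j = 0; j < Kb; ++j) {
            const double m2 = p2[j];
            for (int i = 0; i < Ka; ++i, ++idx) {
              double m = p1[i] * m2;
              m = m < 1e-12 ? 1e-12 : (m > 1e12 ? 1e12 : m);
              accn[idx] *= m;
              accd[idx] *= 1.0 + m;
            }
          }
        }
      }
    }
    if (++in_chunk == CHUNK) {
      for (R_xlen_t n = 0; n < N; ++n) {
        ll[n] += std::log(accn[n]) - std::log(accd[n]);
        accn[n] = 1.0;
        accd[n] = 1.0;
      }
      in_chunk = 0;
    }
  }
  if (in_chunk > 0)
    for (R_xlen_t n = 0; n < N; ++n)
      ll[n] += std::log(accn[n]) - std::log(accd[n]);

  if (tie_betas)
    ll.attr("dim") = IntegerVector::create(Ka, Kb, Ku);
  else
    ll.attr("dim") = IntegerVector::create(Ka, Kb, Ku, Kl);
  return ll;
}
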